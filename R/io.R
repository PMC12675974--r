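#' Convert CO2 mole fraction to partial pressure
#'
#' `umol mol-1` (ppm) to Pa at a given total pressure, and back. 400
#' umol mol-1 at 101.325 kPa is 40.53 Pa.
#'
#' @param x Values to convert.
#' @param pressure_kpa Total pressure in kPa.
#' @return Converted values.
#' @export
co2_umol_to_pa <- function(x, pressure_kpa = 101.325) {
  x * 1e-6 * pressure_kpa * 1000
}

#' @rdname co2_umol_to_pa
#' @export
co2_pa_to_umol <- function(x, pressure_kpa = 101.325) {
  x / (1e-6 * pressure_kpa * 1000)
}

# Comma-separated gas-exchange dialect: one comment line of the form
#   # pressure_kpa=101.325 co2_units=Pa basis=cc temp_c=6
# followed by a header `light,co2,a_net` and numeric rows.

#' Read a gas-exchange table
#'
#' Reads the package's plain-text gas-exchange dialect: a `#` metadata
#' comment declaring total pressure, CO2 units (`Pa` or `umol_mol`),
#' basis (`cc` or `ci`) and leaf temperature, then CSV columns `light`,
#' `co2`, `a_net`. CO2 mole fractions are converted to Pa with the
#' declared pressure; rows are grouped into one curve per light level
#' and sorted by CO2.
#'
#' @param path File path.
#' @return A tibble with columns `light`, `cc` (or `ci`), `a_net` and
#'   attributes `temp`, `basis`, `pressure_kpa`.
#' @seealso [write_gas_exchange()]
#' @export
read_gas_exchange <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  meta_line <- grep("^#", lines, value = TRUE)
  if (length(meta_line) < 1) abort("read_gas_exchange: missing `#` metadata line")
  meta <- .parse_meta(meta_line[1])
  units <- meta$co2_units %||% "Pa"
  basis <- meta$basis %||% "cc"
  if (!basis %in% c("cc", "ci")) abort("read_gas_exchange: basis must be `cc` or `ci`")
  pressure <- as.numeric(meta$pressure_kpa %||% 101.325)

  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  header <- strsplit(body[1], ",")[[1]]
  required <- c("light", "co2", "a_net")
  if (!all(required %in% header)) {
    abort(paste0("read_gas_exchange: missing column(s): ",
                 paste(setdiff(required, header), collapse = ", ")))
  }
  rows <- strsplit(body[-1], ",")
  bad_len <- which(lengths(rows) != length(header))
  if (length(bad_len)) {
    abort(paste0("read_gas_exchange: malformed row(s): ",
                 paste(bad_len, collapse = ", ")))
  }
  mat <- do.call(rbind, rows)
  colnames(mat) <- header
  df <- as_tibble(mat)[, required]
  parsed <- suppressWarnings(lapply(df, as.numeric))
  for (col in required) {
    bad <- which(is.na(parsed[[col]]))
    if (length(bad)) {
      abort(sprintf("read_gas_exchange: non-numeric `%s` in data row(s) %s",
                    col, paste(bad, collapse = ", ")))
    }
  }
  out <- as_tibble(parsed)
  if (identical(units, "umol_mol")) {
    out$co2 <- co2_umol_to_pa(out$co2, pressure)
  } else if (!identical(units, "Pa")) {
    abort("read_gas_exchange: co2_units must be `Pa` or `umol_mol`")
  }
  dup <- duplicated(out[, c("light", "co2")])
  if (any(dup)) {
    abort(sprintf("read_gas_exchange: duplicate (light, co2) in data row(s) %s",
                  paste(which(dup), collapse = ", ")))
  }
  out <- out %>% arrange(dplyr::desc(.data$light), .data$co2)
  names(out)[names(out) == "co2"] <- basis
  attr(out, "basis") <- basis
  attr(out, "temp") <- if (!is.null(meta$temp_c)) as.numeric(meta$temp_c) else NA_real_
  attr(out, "pressure_kpa") <- pressure
  out
}

.parse_meta <- function(line) {
  line <- sub("^#\\s*", "", line)
  kv <- strsplit(trimws(strsplit(line, "[ ,]+")[[1]]), "=")
  kv <- kv[lengths(kv) == 2]
  setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}

#' Write a gas-exchange table
#'
#' Writes the dialect read by [read_gas_exchange()]. CO2 values are
#' written in Pa.
#'
#' @param data Tibble with `light`, `a_net` and `cc` or `ci`.
#' @param path Output file path.
#' @param temp Leaf temperature (C); defaults to the `temp` attribute.
#' @param pressure_kpa Total pressure recorded in the metadata.
#' @param basis CO2 basis; defaults to the `basis` attribute, else the
#'   CO2 column present.
#' @return `path`, invisibly.
#' @export
write_gas_exchange <- function(data, path, temp = NULL,
                               pressure_kpa = 101.325, basis = NULL) {
  basis <- basis %||% attr(data, "basis") %||% (if (!is.null(data$ci)) "ci" else "cc")
  temp <- temp %||% attr(data, "temp") %||% NA_real_
  co2 <- laisk_co2(data, basis)
  meta <- sprintf("# pressure_kpa=%s co2_units=Pa basis=%s temp_c=%s",
                  format(pressure_kpa, digits = 12), basis, format(temp, digits = 12))
  body <- sprintf("%s,%s,%s",
                  format(data$light, digits = 15, trim = TRUE, scientific = FALSE),
                  format(co2, digits = 15, trim = TRUE),
                  format(data$a_net, digits = 15, trim = TRUE))
  writeLines(c(meta, "light,co2,a_net", body), path)
  invisible(path)
}
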