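# pressure_kpa=101.325 co2_units=Pa basis=cc temp_c=6
light,co2,a_net
300,1.2,-1.9871
300,2.2,-0.2204
300,3.2,1.6238
300,4.2,2.8205
300,5.2,3.6907
300,6.2,4.6600
300,7.2,5.0558
300,8.2,5.8364
300,9.2,6.2416
150,1.2,-1.8120
150,2.2,-0.1980
150,3.2,0.8076
150,4.2,1.6878
150,5.2,2.3993
150,6.2,2.8938
150,7.2,3.2502
150,8.2,3.5799
150,9.2,4.1257
80,1.2,-1.5051
80,2.2,-0.5456
80,3.2,0.0171
80,4.2,0.5240
80,5.2,0.9635
80,6.2,1.2706
80,7.2,1.4460
80,8.2,1.7170
80,9.2,1.8533
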