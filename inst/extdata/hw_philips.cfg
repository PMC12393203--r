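# Philips-style hardware profile: 6.4 us gradient grid
name philips_7t
max_gradient 1.5e6
max_slew 8e9
gradient_raster 6.4e-6
rf_raster 1e-6
max_adc_bandwidth 2e6
peak_power 3000
avg_power 20
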