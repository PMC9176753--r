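# Synthetic dilution series emulating haploid budding yeast in glucose
# measured on a plate reader with a saturating response at high OD.
# Columns: measured OD, dilution factor.
1.43247 1
1.14842 0.68517549
0.88928 0.46946546
0.664681 0.32166622
0.483228 0.22039781
0.343612 0.15101118
0.24869 0.10346916
0.169231 0.070894533
0.125898 0.048575196
0.0812484 0.033282534
0.0614255 0.022804377
0.0478301 0.015625
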