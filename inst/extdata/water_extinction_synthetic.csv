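# Synthetic digitization of the water extinction coefficient k(lambda),
# 1.2-2.0 um band. Follows the published spectral shape; knots at the
# 1470 and 1875 nm stimulation wavelengths are set from absorption
# coefficients reported in the infrared neurostimulation literature
# (k = alpha * lambda / (4 pi)). Not a verbatim copy of any dataset.
wavelength_nm,k
1200,9.931268e-06
1300,1.220718e-05
1350,3.222888e-05
1400,1.336902e-04
1450,3.323155e-04
1470,2.902831e-04
1500,2.339578e-04
1550,1.171778e-04
1600,8.530705e-05
1650,7.221656e-05
1700,7.575775e-05
1750,9.051937e-05
1800,1.145916e-04
1850,2.944366e-04
1875,4.009959e-04
1900,9.071832e-04
1950,1.862113e-03
2000,1.098169e-03
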