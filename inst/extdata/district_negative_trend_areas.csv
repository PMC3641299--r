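zone,low_ha,low_pct,med_ha,med_pct,high_ha,high_pct
Bagat,7398.91,16.67,979.90,2.21,2865.47,6.46
Gurlen,9636.70,22.92,1110.32,2.64,3529.58,8.39
Khanka,10394.84,22.89,1913.06,4.21,5126.04,11.29
Khazarasp,9415.64,18.07,1147.32,2.20,3839.87,7.37
Khiva,10080.17,21.77,1429.34,3.09,5754.96,12.43
Kushkhupyr,11981.58,21.91,1649.20,3.02,5792.80,10.59
Shavat,10040.41,24.07,1644.60,3.94,5006.26,12.00
Urgench,10897.64,22.74,1617.68,3.38,5278.79,11.01
Yangiaryk,10102.87,24.59,1456.93,3.55,6054.39,14.74
Yangibazar,8096.92,22.65,1726.44,4.83,4280.70,11.97
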