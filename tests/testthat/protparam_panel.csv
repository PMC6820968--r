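seq,pmw,pi,arom,instab,gravy
DAEFRHDSGYEVHHQKLVFF,2461.6439,5.7558,0.2,16.5,-0.78
MKWVTFISLLFLFSSAYSRG,2353.7775,9.9924,0.25,22.195,0.865
EAKIIFEVDWQCADHITYAV,2351.6311,4.3083,0.15,23.535,0.255
HVQIRWKAGQMKFHMEDPEN,2481.8093,6.9256,0.1,56.46,-1.275
NYKCRVEPDVLYNWHDCILD,2495.7861,4.8285,0.15,31.645,-0.61
IEPKRNGNNHKDYGVIGRPK,2292.5558,9.993,0.05,69.035,-1.695
VIMCICMPKDHWMHSPRFKF,2507.0968,8.9017,0.15,97.495,0.12
IVVKWQWPNIFTSDCEFGQY,2460.7584,4.3703,0.25,22.015,-0.125
DPPYRTKVAEVKMELQGRAK,2316.6784,9.5244,0.05,37.59,-1.13
TGTELTYHFNGVTAYMSAEN,2206.3439,4.5046,0.15,43.805,-0.395
LICIWDDSDVFFSVGKTYQH,2373.6365,4.4133,0.2,10.64,0.165
VHLPNRTREIIDMAWVIWIA,2433.8707,6.7233,0.1,30.685,0.445
DCIDCMDTIKSHVFWWSISQ,2414.7333,4.4133,0.15,23.67,0.07
HEEQNQQRCECPMEIHHVRF,2550.8102,5.782,0.05,84.92,-1.49
QGKRIDRVECVADIGQSSHP,2195.4159,6.7461,0.0,61.9,-0.795
CGPAPKRLQVSFHLHCWVCM,2312.8036,8.7075,0.1,81.485,0.32
YCYDQWWTMKHMIKPFLRMD,2693.1941,8.1641,0.25,25.07,-0.67
ARYWEDVHTKFNDINLGRVL,2446.7171,6.7986,0.15,6.405,-0.59
YTAVLEFKEEVFKLYHMHKT,2513.9057,6.9249,0.2,48.93,-0.365
SKCDQKCAMFKGRVQVAEDF,2290.6409,7.767,0.1,9.46,-0.52
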