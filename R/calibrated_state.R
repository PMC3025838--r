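# ---------------------------------------------------------------------------
# The calibrated quiescent (G0) state: initial amounts for every populated
# pool, computed by relaxing the model without mitogen to its fixed point
# and frozen here as part of the calibrated parameter set (initial amounts
# are fitted parameters of the model, like the rate constants).  States not
# listed start at zero.
# ---------------------------------------------------------------------------

cc_calibrated_state <- function() c(
  "aa.cytosol" = 2.7139308e+08,
  "aa.on_trna" = 6776498.9,
  "aa.in_protein" = 2.957225e+10,
  "aa.trash" = 1.1790511e+09,
  "nt.cytosol" = 9.6966086e+08,
  "nt.in_rna" = 1.2175117e+09,
  "nt.trash" =  17559035,
  "atp.atp" = 1.0992042e+09,
  "atp.adp" = 9814345.9,
  "atp.amp" = 981434.12,
  "rrna.nascent" = 6897.3398,
  "rrna.in_ribosome" = 103151.67,
  "rrna.trash" = 1448.4146,
  "ribo.assembling" = 1378.0894,
  "ribo.free" = 45182.416,
  "ribo.translating" = 22591.167,
  "ribo.trash" = 1379.4412,
  "trna.free" = 4552.1663,
  "trna.trash" = 91.043291,
  "snrna.free" = 752.43591,
  "snrna.spliceosome" = 7524.0474,
  "snrna.trash" = 82.764799,
  "mrna.nascent" = 1120.6898,
  "mrna.nuclear" = 1911.0504,
  "mrna.cytosol" = 25231.947,
  "mrna.ribosome_bound" = 15686.841,
  "mrna.trash" = 28968.906,
  "rnapol.unfold" = 10.612215,
  "rnapol.sequestered" = 28019.282,
  "rnapol.active" = 3808.7797,
  "rnapol.transcribing" = 1904.3422,
  "rnapol.trash" = 107.16037,
  "prot.unfold" = 121869.53,
  "prot.cytosol" =  43524583,
  "prot.nucleus" = 4352443.7,
  "prot.in_use" =  13057331,
  "prot.trash" = 1019634.8,
  "lipid.precursor" = 971498.18,
  "lipid.membrane" =  58289640,
  "lipid.trash" = 2914481.4,
  "glc.cytosol" = 9.2954821e+08,
  "p27.unf" = 200.38917,
  "p27.cyt" = 1648.7355,
  "p27.nuc" =  20051.05,
  "p27.cycd_c" = 2.0039349,
  "p27.cdk2_c" = 4.5622901,
  "p27.ubq" =  133.7705,
  "p27.trash" = 2514.8801,
  "rb.unf" =  104.5592,
  "rb.cyt" = 820.30601,
  "rb.nuc" = 9854.6716,
  "rb.e2f_c" = 2154.4197,
  "rb.pho" = 240.48188,
  "rb.pho2" = 1.5610215e-09,
  "rb.trash" = 1312.2157,
  "cycd.unf" = 0.01742363,
  "cycd.cyt" = 0.031426284,
  "cycd.nuc" = 0.042088772,
  "cycd.cdk_c" = 0.00022006082,
  "cycd.cdk_p27" = 2.0039349,
  "cycd.ubq" = 0.0040112135,
  "cycd.trash" = 0.21866618,
  "cdk2.unf" = 174.25535,
  "cdk2.cyt" = 1613.4733,
  "cdk2.nuc" = 20168.411,
  "cdk2.in_use" = 4.5618834,
  "cdk2.trash" = 2186.9008,
  "cdk1.unf" = 87.137205,
  "cdk1.cyt" = 806.82486,
  "cdk1.nuc" = 10085.308,
  "cdk1.in_use" = 1.0738872,
  "cdk1.trash" =   1093.57,
  "cyce.unf" = 0.036993463,
  "cyce.cyt" = 0.060874302,
  "cyce.nuc" = 0.00045284414,
  "cyce.cdk2_i" = 0.00047821484,
  "cyce.cdk2_a" = 1.8383327e-09,
  "cyce.ubq" = 3.0326404e-06,
  "cyce.trash" = 0.46426668,
  "bmyb.unf" = 0.022316088,
  "bmyb.cyt" = 0.18363643,
  "bmyb.nuc" = 2.2333715,
  "bmyb.ubq" = 0.014899929,
  "bmyb.trash" = 0.28006637,
  "nfy.unf" = 3.5070421,
  "nfy.cyt" = 32.472567,
  "nfy.nuc" = 405.90698,
  "nfy.act" = 1.502937e-09,
  "nfy.on_dna" = 1.4734676e-09,
  "nfy.trash" =   44.0133,
  "e2f.unf" =  17.47367,
  "e2f.cyt" = 28.770682,
  "e2f.nuc" = 0.47262454,
  "e2f.on_dna" = 0.46335738,
  "e2f.pho" = 1.940254e-07,
  "e2f.ubq" = 0.0031531126,
  "e2f.trash" = 219.29417,
  "tfg.unf" = 0.075592455,
  "tfg.cyt" = 0.35045373,
  "tfg.nuc" = 3.4370855,
  "tfg.on_dna" = 3.3696915,
  "tfg.pho" = 1.7175058,
  "tfg.ubq" = 0.022971776,
  "tfg.trash" = 0.94868244,
  "eif4.unf" = 348.49002,
  "eif4.cyt" = 40650.608,
  "eif4.act" = 2650.7013,
  "eif4.in_use" = 259.87266,
  "eif4.trash" =  4373.542,
  "cycc.unf" = 174.25372,
  "cycc.cyt" = 314.29426,
  "cycc.nuc" = 420.92981,
  "cycc.cdk8_c" = 21046.456,
  "cycc.trash" = 2186.8803,
  "kpc.unf" = 17.441054,
  "kpc.nuc" = 2180.1282,
  "kpc.trash" = 218.88483,
  "cyca.unf" = 6.4199816,
  "cyca.trash" = 0.32099901,
  "scf.unf" = 29.637595,
  "scf.nuc" = 47.358851,
  "scf.ubq" =  146.2936,
  "scf.trash" = 371.95172,
  "skp2.unf" = 15.698691,
  "skp2.cyt" = 37.717115,
  "skp2.nuc" = 180.83289,
  "skp2.scf_c" = 33.385038,
  "skp2.ubq" = 68.416031,
  "skp2.trash" = 197.01848,
  "btrc.unf" = 0.020685269,
  "btrc.cyt" = 0.053684346,
  "btrc.nuc" = 0.29887035,
  "btrc.scf_c" = 0.036211037,
  "btrc.pho" = 0.0099623323,
  "btrc.ubq" = 0.087477185,
  "btrc.trash" = 0.25959998,
  "fbw7.unf" = 0.020685269,
  "fbw7.cyt" = 0.055758037,
  "fbw7.nuc" = 0.33039046,
  "fbw7.dimer" = 0.2753253,
  "fbw7.scf_c" = 0.12026159,
  "fbw7.ubq" = 0.072156864,
  "fbw7.trash" = 0.25959991,
  "rc.unf" = 0.082656407,
  "rc.cyt" = 0.16317157,
  "rc.nuc" = 0.41379772,
  "rc.dna_b" = 0.17571956,
  "rc.ubq" = 0.38317435,
  "rc.trash" = 1.0373373,
  "dnapol.unf" = 0.021500679,
  "dnapol.cyt" = 0.17692652,
  "dnapol.nuc" = 2.1517663,
  "dnapol.ubq" = 0.014355499,
  "dnapol.trash" = 0.26983301,
  "wee1.unf" = 52.288314,
  "wee1.cyt" = 128.15763,
  "wee1.act" = 6407.8709,
  "wee1.pho" = 1.7635373e-07,
  "wee1.react" = 7.0541416e-07,
  "wee1.trash" = 656.21717,
  "cycb.unf" = 0.036993463,
  "cycb.cyt" = 0.022473948,
  "cycb.cdk1_i" = 1.0738864,
  "cycb.cdk1_a" = 9.3165515e-07,
  "cycb.cdk1_n" = 4.6582636e-09,
  "cycb.ubq" = 0.14111274,
  "cycb.trash" = 0.46426753,
  "cdc25a.unf" = 5.2628958,
  "cdc25a.cyt" = 9.7317132,
  "cdc25a.nuc" = 16.349648,
  "cdc25a.act" = 0.011865269,
  "cdc25a.ubq" = 25.270747,
  "cdc25a.trash" = 66.049323,
  "cdc25b.unf" =  0.044405,
  "cdc25b.cyt" = 0.37534044,
  "cdc25b.act" = 0.00039981024,
  "cdc25b.ubq" = 0.019324598,
  "cdc25b.nuc" = 4.6917529,
  "cdc25b.trash" = 0.55728087,
  "cdc25c.unf" = 8.7292387,
  "cdc25c.cyt" = 80.826172,
  "cdc25c.cyt_a" = 1.1285966e-05,
  "cdc25c.nuc" = 1010.3269,
  "cdc25c.act" = 3.3739812e-08,
  "cdc25c.trash" = 109.55175,
  "plk1.unf" = 0.12534911,
  "plk1.cyt" =   2.01986,
  "plk1.act" = 1.8802588e-09,
  "plk1.nuc" = 3.1337621e-09,
  "plk1.ubq" = 0.54595074,
  "plk1.trash" = 1.5731297,
  "emi1.unf" = 0.058194115,
  "emi1.cyt" = 0.096164529,
  "emi1.nuc" = 0.0068480111,
  "emi1.cdc20_c" =  7.170288,
  "emi1.cdh1_c" = 0.00071136691,
  "emi1.ubq" = 9.283522e-06,
  "emi1.trash" = 0.73033391,
  "apc.unf" = 87.135574,
  "apc.cyt" = 727.29338,
  "apc.nuc" = 8876.4703,
  "apc.cdh1_c" = 1288.1653,
  "apc.cdc20_i" = 2.2711101e-08,
  "apc.trash" = 1093.5495,
  "cdh1.unf" = 10.471602,
  "cdh1.cyt" = 17.237392,
  "cdh1.nuc" = 0.21832743,
  "cdh1.in_apc" = 1288.1653,
  "cdh1.pho" = 3.3018224,
  "cdh1.ubq" = 0.0010101972,
  "cdh1.trash" = 131.41837,
  "cdc20.unf" = 13.956328,
  "cdc20.cyt" = 37.432455,
  "cdc20.nuc" = 220.06513,
  "cdc20.in_apc" = 3.825667e-05,
  "cdc20.ubq" = 59.481713,
  "cdc20.trash" = 175.15183,
  "cdc14.unf" = 17.441054,
  "cdc14.cyt" = 161.20955,
  "cdc14.nuc" = 2014.3589,
  "cdc14.securin_c" =  4.559705,
  "cdc14.act" = 3.754351e-09,
  "cdc14.react" = 1.4722944e-09,
  "cdc14.trash" = 218.88483,
  "securin.unf" = 0.036993463,
  "securin.cyt" = 0.061068076,
  "securin.nuc" = 0.0033982122,
  "securin.cdc14_c" =  4.559705,
  "securin.trash" = 0.46426668,
  "oric.free" = 14999.824,
  "oric.fired" = 1.3418773e-06,
  "dna.nt" =     6e+09,
  "m_p27.nascent" = 1.8412898,
  "m_p27.nuclear" = 3.1398498,
  "m_p27.cytosol" =  43.67119,
  "m_p27.ribosome_bound" = 23.611272,
  "m_p27.trash" = 47.595821,
  "m_rb.nascent" = 0.96074952,
  "m_rb.nuclear" = 1.6383131,
  "m_rb.cytosol" = 22.786785,
  "m_rb.ribosome_bound" = 12.319906,
  "m_rb.trash" = 24.834581,
  "m_cycd.nascent" = 0.00016009824,
  "m_cycd.nuclear" = 0.00027300668,
  "m_cycd.cytosol" = 0.0037971646,
  "m_cycd.ribosome_bound" = 0.0020529755,
  "m_cycd.trash" = 0.0041384071,
  "m_cdk2.nascent" = 1.6011575,
  "m_cdk2.nuclear" = 2.7303653,
  "m_cdk2.cytosol" = 37.975799,
  "m_cdk2.ribosome_bound" =    20.532,
  "m_cdk2.trash" = 41.388597,
  "m_cyce.nascent" = 0.0003399171,
  "m_cyce.nuclear" = 0.00057964184,
  "m_cyce.cytosol" = 0.0080620554,
  "m_cyce.ribosome_bound" = 0.0043588319,
  "m_cyce.trash" = 0.0087865724,
  "m_bmyb.nascent" = 0.00020505295,
  "m_bmyb.nuclear" = 0.00034966547,
  "m_bmyb.cytosol" = 0.0048633873,
  "m_bmyb.ribosome_bound" = 0.0026294396,
  "m_bmyb.trash" = 0.0053004484,
  "m_nfy.nascent" = 0.032224701,
  "m_nfy.nuclear" = 0.054951001,
  "m_nfy.cytosol" = 0.76429631,
  "m_nfy.ribosome_bound" = 0.41322454,
  "m_nfy.trash" = 0.83298188,
  "m_e2f.nascent" = 0.16055803,
  "m_e2f.nuclear" = 0.27379074,
  "m_e2f.cytosol" = 3.8080699,
  "m_e2f.ribosome_bound" = 2.0588716,
  "m_e2f.trash" = 4.1502925,
  "m_cyca.nascent" = 0.00023502276,
  "m_cyca.nuclear" = 0.00040077133,
  "m_cyca.cytosol" = 0.0055742024,
  "m_cyca.ribosome_bound" = 0.003013749,
  "m_cyca.trash" = 0.0060751427,
  "m_scf.nascent" = 0.2723271,
  "m_scf.nuclear" = 0.46438436,
  "m_scf.cytosol" =  6.458977,
  "m_scf.ribosome_bound" = 3.4921114,
  "m_scf.trash" = 7.0394306,
  "m_skp2.nascent" = 0.14424851,
  "m_skp2.nuclear" = 0.24597901,
  "m_skp2.cytosol" = 3.4212453,
  "m_skp2.ribosome_bound" = 1.8497309,
  "m_skp2.trash" = 3.7287048,
  "m_btrc.nascent" = 0.00019006805,
  "m_btrc.nuclear" = 0.00032411254,
  "m_btrc.cytosol" = 0.0045079797,
  "m_btrc.ribosome_bound" = 0.0024372849,
  "m_btrc.trash" = 0.0049131013,
  "m_fbw7.nascent" = 0.00019006805,
  "m_fbw7.nuclear" = 0.00032411254,
  "m_fbw7.cytosol" = 0.0045079797,
  "m_fbw7.ribosome_bound" = 0.0024372849,
  "m_fbw7.trash" = 0.0049131013,
  "m_tfg.nascent" = 0.0006945868,
  "m_tfg.nuclear" = 0.0011844405,
  "m_tfg.cytosol" = 0.016474007,
  "m_tfg.ribosome_bound" = 0.0089068385,
  "m_tfg.trash" = 0.017954484,
  "m_rc.nascent" = 0.00075949445,
  "m_rc.nuclear" = 0.0012951239,
  "m_rc.cytosol" = 0.018013467,
  "m_rc.ribosome_bound" = 0.0097391634,
  "m_rc.trash" = 0.019632291,
  "m_dnapol.nascent" = 0.0001975605,
  "m_dnapol.nuclear" = 0.000336889,
  "m_dnapol.cytosol" = 0.0046856835,
  "m_dnapol.ribosome_bound" = 0.0025333623,
  "m_dnapol.trash" = 0.0051067749,
  "m_wee1.nascent" = 0.48045481,
  "m_wee1.nuclear" = 0.81929303,
  "m_wee1.cytosol" = 11.395291,
  "m_wee1.ribosome_bound" = 6.1609796,
  "m_wee1.trash" =  12.41936,
  "m_cycb.nascent" = 0.0003399171,
  "m_cycb.nuclear" = 0.00057964184,
  "m_cycb.cytosol" = 0.0080620554,
  "m_cycb.ribosome_bound" = 0.0043588319,
  "m_cycb.trash" = 0.0087865724,
  "m_cdk1.nascent" = 0.80066627,
  "m_cdk1.nuclear" = 1.3653319,
  "m_cdk1.cytosol" = 18.989976,
  "m_cdk1.ribosome_bound" = 10.267123,
  "m_cdk1.trash" = 20.696561,
  "m_cdc25c.nascent" = 0.080209217,
  "m_cdc25c.nuclear" = 0.13677634,
  "m_cdc25c.cytosol" = 1.9023795,
  "m_cdc25c.ribosome_bound" = 1.0285407,
  "m_cdc25c.trash" =  2.073342,
  "m_plk1.nascent" = 0.0011517799,
  "m_plk1.nuclear" = 0.0019640665,
  "m_plk1.cytosol" = 0.027317569,
  "m_plk1.ribosome_bound" = 0.01476952,
  "m_plk1.trash" = 0.029772522,
  "m_emi1.nascent" = 0.00053472087,
  "m_emi1.nuclear" = 0.00091182993,
  "m_emi1.cytosol" = 0.012682354,
  "m_emi1.ribosome_bound" = 0.0068568429,
  "m_emi1.trash" = 0.013822085,
  "m_apc.nascent" = 0.80065129,
  "m_apc.nuclear" = 1.3653064,
  "m_apc.cytosol" =  18.98962,
  "m_apc.ribosome_bound" = 10.266931,
  "m_apc.trash" = 20.696174,
  "m_cdh1.nascent" = 0.096219041,
  "m_cdh1.nuclear" = 0.16407701,
  "m_cdh1.cytosol" = 2.2820959,
  "m_cdh1.ribosome_bound" = 1.2338383,
  "m_cdh1.trash" = 2.4871827,
  "m_cdc20.nascent" = 0.12823869,
  "m_cdc20.nuclear" = 0.21867835,
  "m_cdc20.cytosol" = 3.0415289,
  "m_cdc20.ribosome_bound" = 1.6444334,
  "m_cdc20.trash" = 3.3148641,
  "m_cdc14.nascent" = 0.16025834,
  "m_cdc14.nuclear" = 0.27327968,
  "m_cdc14.cytosol" = 3.8009618,
  "m_cdc14.ribosome_bound" = 2.0550285,
  "m_cdc14.trash" = 4.1425456,
  "m_cdc25a.nascent" = 0.048358484,
  "m_cdc25a.nuclear" = 0.082463051,
  "m_cdc25a.cytosol" = 1.1469528,
  "m_cdc25a.ribosome_bound" = 0.62011167,
  "m_cdc25a.trash" = 1.2500269,
  "m_cdc25b.nascent" = 0.00040801864,
  "m_cdc25b.nuclear" = 0.00069577162,
  "m_cdc25b.cytosol" = 0.0096772657,
  "m_cdc25b.ribosome_bound" = 0.0052321117,
  "m_cdc25b.trash" = 0.010546936,
  "m_securin.nascent" = 0.0003399171,
  "m_securin.nuclear" = 0.00057964184,
  "m_securin.cytosol" = 0.0080620554,
  "m_securin.ribosome_bound" = 0.0043588319,
  "m_securin.trash" = 0.0087865724,
  "m_cycc.nascent" = 1.6011425,
  "m_cycc.nuclear" = 2.7303398,
  "m_cycc.cytosol" = 37.975443,
  "m_cycc.ribosome_bound" = 20.531808,
  "m_cycc.trash" =  41.38821,
  "m_kpc.nascent" = 0.16025834,
  "m_kpc.nuclear" = 0.27327968,
  "m_kpc.cytosol" = 3.8009618,
  "m_kpc.ribosome_bound" = 2.0550285,
  "m_kpc.trash" = 4.1425456,
  "m_rnapol.nascent" = 0.039237527,
  "m_rnapol.nuclear" = 0.066909586,
  "m_rnapol.cytosol" = 0.93062453,
  "m_rnapol.ribosome_bound" = 0.50315158,
  "m_rnapol.trash" = 1.0142576,
  "m_eif4.nascent" = 3.2021249,
  "m_eif4.nuclear" = 5.4604065,
  "m_eif4.cytosol" = 75.947089,
  "m_eif4.ribosome_bound" = 41.061563,
  "m_eif4.trash" = 82.772281
)

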