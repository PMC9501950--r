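compound_id,concentration_ppm,inhibition_pct
ascorbic_acid,0.400399214846883,7.97535290971416
ascorbic_acid,0.800798429693765,15.0776469797198
ascorbic_acid,1.60159685938753,26.9498902030838
ascorbic_acid,3.20319371877506,40.4849223676106
ascorbic_acid,6.40638743755012,58.4846229815239
ascorbic_acid,12.8127748751002,74.0752756895798
ascorbic_acid,25.6255497502005,86.1810994931192
ascorbic_acid,51.251099500401,91.438505535906
citflavanone,48.5004541215853,7.96479250554343
citflavanone,97.0009082431706,14.934223407674
citflavanone,194.001816486341,26.2555804661285
citflavanone,388.003632972682,40.4668989317324
citflavanone,776.007265945365,58.8080176114081
citflavanone,1552.01453189073,73.9241234107108
citflavanone,3104.02906378146,85.1230618889626
citflavanone,6208.05812756292,93.930829603538
lonchocarpol_A,39.0225716032561,7.98445805717535
lonchocarpol_A,78.0451432065122,15.4380304623304
lonchocarpol_A,156.090286413024,25.4645088173666
lonchocarpol_A,312.180572826049,41.4794644076226
lonchocarpol_A,624.361145652098,60.5837214667493
lonchocarpol_A,1248.7222913042,72.9887603427216
lonchocarpol_A,2497.44458260839,84.1754154595121
lonchocarpol_A,4994.88916521678,90.7114244545854
lupinifolin,11.3702770414797,8.49252638482574
lupinifolin,22.7405540829594,14.6625497535864
lupinifolin,45.4811081659187,25.7576837082061
lupinifolin,90.9622163318375,41.0798015732461
lupinifolin,181.924432663675,57.4414292055029
lupinifolin,363.84886532735,72.4799189979077
lupinifolin,727.6977306547,86.2493955618286
lupinifolin,1455.3954613094,91.6640551727611
quercetin,0.719481149857312,7.99648683720222
quercetin,1.43896229971462,14.7768119332287
quercetin,2.87792459942925,26.0464484183607
quercetin,5.7558491988585,41.191380700633
quercetin,11.511698397717,59.0898090901752
quercetin,23.023396795434,72.1258988589103
quercetin,46.046793590868,87.0037401525517
quercetin,92.093587181736,91.8455434865641
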