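 ---------------------------------------------------------------
 Two-body FMO pair interaction energies / PIEDA, units: kcal/mol
 ---------------------------------------------------------------
    I    J  DL   Z         R   Q(I->J)          dE        dD*V         total           Ees           Eex       Ect+mix         Edisp
    1    2   0   0    6.0000    0.0000      0.0000      0.0000     -2.267407     -1.247074      0.113370     -0.340111     -0.793592
    1    7   0   0    7.0000    0.0000      0.0000      0.0000     -5.018757     -2.760316      0.250938     -0.752814     -1.756565
    1    8   0   0   18.9737    0.0000      0.0000      0.0000      0.139510      0.076731      0.006975      0.020926      0.034878
    2    3   0   0    6.0000    0.0000      0.0000      0.0000     -2.952049     -1.623627      0.147602     -0.442807     -1.033217
    3    4   0   0    6.0000    0.0000      0.0000      0.0000     -2.638716     -1.451294      0.131936     -0.395807     -0.923551
    4    5   0   0    6.0000    0.0000      0.0000      0.0000     -2.306783     -1.268731      0.115339     -0.346017     -0.807374
    5    6   0   0    6.0000    0.0000      0.0000      0.0000     -2.530202     -1.391611      0.126510     -0.379530     -0.885571
    5   11   0   0    7.0000    0.0000      0.0000      0.0000     -5.787302     -3.183016      0.289365     -0.868095     -2.025556
    6   12   0   0    7.0000    0.0000      0.0000      0.0000     -5.242984     -2.883641      0.262149     -0.786448     -1.835044
    7    8   0   0   12.5300    0.0000      0.0000      0.0000     -2.843090     -1.563700      0.142155     -0.426464     -0.995081
    8    9   0   0    6.0000    0.0000      0.0000      0.0000     -3.453068     -1.899187      0.172653     -0.517960     -1.208574
    9   10   0   0    6.0000    0.0000      0.0000      0.0000     -1.598120     -0.878966      0.079906     -0.239718     -0.559342
   10   11   0   0   12.5300    0.0000      0.0000      0.0000     -2.983436     -1.640890      0.149172     -0.447515     -1.044203
   11   12   0   0    6.0000    0.0000      0.0000      0.0000     -2.676559     -1.472107      0.133828     -0.401484     -0.936796
   12   13   0   0   12.5300    0.0000      0.0000      0.0000     -1.946531     -1.070592      0.097327     -0.291980     -0.681286
   13   14   0   0    6.0000    0.0000      0.0000      0.0000     -2.216838     -1.219261      0.110842     -0.332526     -0.775893
   14   15   0   0    6.0000    0.0000      0.0000      0.0000     -1.467846     -0.807315      0.073392     -0.220177     -0.513746
   15   16   0   0    6.0000    0.0000      0.0000      0.0000     -1.765361     -0.970949      0.088268     -0.264804     -0.617876
   16   17   0   0    6.0000    0.0000      0.0000      0.0000     -3.325750     -1.829163      0.166288     -0.498862     -1.164013
   17   18   0   0    6.0000    0.0000      0.0000      0.0000     -2.398682     -1.319275      0.119934     -0.359802     -0.839539

 FRAGMENT NAMES
 FRAGMENT 1 A:1:ALA
 FRAGMENT 2 A:2:ALA
 FRAGMENT 3 A:3:ALA
 FRAGMENT 4 A:4:ALA
 FRAGMENT 5 A:5:ALA
 FRAGMENT 6 A:6:ALA
 FRAGMENT 7 B:1:ALA
 FRAGMENT 8 B:2:ALA
 FRAGMENT 9 B:4:ALA
 FRAGMENT 10 B:5:ALA
 FRAGMENT 11 B:6:ALA
 FRAGMENT 12 B:7:ALA
 FRAGMENT 13 B:8:ALA
 FRAGMENT 14 B:9:ALA
 FRAGMENT 15 B:10:ALA
 FRAGMENT 16 B:11:ALA
 FRAGMENT 17 B:12:ALA
 FRAGMENT 18 B:13:ALA
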