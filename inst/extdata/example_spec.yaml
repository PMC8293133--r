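schema_version: 1
shared:
  state_costs:
    healthy:
      family: gamma
      mean: 99.28320461884141
      se: 49.641602309420705
    acute_gu:
      family: gamma
      mean: 1871.687394306063879
      se: 935.84369715303194
    acute_gi:
      family: gamma
      mean: 1496.124784229323268
      se: 748.062392114661634
    late_gu:
      family: gamma
      mean: 612.140928395092487
      se: 306.070464197546244
    late_gi:
      family: gamma
      mean: 678.569596465677023
      se: 339.284798232838511
    recurrence:
      family: gamma
      mean: 1280.864034332334995
      se: 640.432017166167498
  salvage_cost:
    family: gamma
    mean: 8470.592620223760605
    se: 4235.296310111880302
  disutilities:
    acute_gu:
      family: beta
      mean: 0.105596790250856
      se: 0.021119358050171
    acute_gi:
      family: beta
      mean: 0.046476617553271
      se: 0.009295323510654
    late_gu:
      family: beta
      mean: 0.177896875683218
      se: 0.035579375136644
    late_gi:
      family: beta
      mean: 0.132901954371482
      se: 0.026580390874296
    recurrence:
      family: beta
      mean: 0.373141944117378
      se: 0.074628388823476
  recurrence_mortality_rr: 2.0
modalities:
  cfIMRT:
    n_fractions: 39
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 16915.0
      se: 1691.5
    event_probs:
      acute_gu:
        family: beta
        mean: 0.192928032099735
        se: 0.038585606419947
      acute_gi:
        family: beta
        mean: 0.143030974909198
        se: 0.02860619498184
      late_gu:
        family: beta
        mean: 0.006582826906815
        se: 0.001316565381363
      late_gi:
        family: beta
        mean: 0.007449246739969
        se: 0.001489849347994
      recurrence:
        family: beta
        mean: 0.007226910896599
        se: 0.00144538217932
  hfIMRT:
    n_fractions: 20
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 11000.0
      se: 1100.0
    event_probs:
      acute_gu:
        family: beta
        mean: 0.414436389738694
        se: 0.082887277947739
      acute_gi:
        family: beta
        mean: 0.286168817151338
        se: 0.057233763430268
      late_gu:
        family: beta
        mean: 0.007286382339895
        se: 0.001457276467979
      late_gi:
        family: beta
        mean: 0.005774684263393
        se: 0.001154936852679
      recurrence:
        family: beta
        mean: 0.004988580327481
        se: 0.000997716065496
  HDR-IMRT:
    n_fractions: 25
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 17725.0
      se: 1772.5
    event_probs:
      acute_gu:
        family: beta
        mean: 0.172091101214755
        se: 0.034418220242951
      acute_gi:
        family: beta
        mean: 0.094139188132249
        se: 0.01882783762645
      late_gu:
        family: beta
        mean: 0.007496182773262
        se: 0.001499236554652
      late_gi:
        family: beta
        mean: 0.004304622309282
        se: 0.000860924461856
      recurrence:
        family: beta
        mean: 0.016317462719977
        se: 0.003263492543995
  HDR-b:
    n_fractions: 2
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 11600.0
      se: 1160.0
    event_probs:
      acute_gu:
        family: beta
        mean: 0.274194734729826
        se: 0.054838946945965
      acute_gi:
        family: beta
        mean: 0.229404627066106
        se: 0.045880925413221
      late_gu:
        family: beta
        mean: 0.009935248758644
        se: 0.001987049751729
      late_gi:
        family: beta
        mean: 0.004280211076606
        se: 0.000856042215321
      recurrence:
        family: beta
        mean: 0.016439123541117
        se: 0.003287824708223
  LDR-b:
    n_fractions: 1
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 11450.0
      se: 1145.0
    event_probs:
      acute_gu:
        family: beta
        mean: 0.427146830887068
        se: 0.085429366177414
      acute_gi:
        family: beta
        mean: 0.103035630320664
        se: 0.020607126064133
      late_gu:
        family: beta
        mean: 0.007213390128687
        se: 0.001442678025737
      late_gi:
        family: beta
        mean: 0.002753330575768
        se: 0.000550666115154
      recurrence:
        family: beta
        mean: 0.008275530699641
        se: 0.001655106139928
  SBRT:
    n_fractions: 5
    mortality_rr: 2.5
    index_cost:
      family: gamma
      mean: 9250.0
      se: 925.0
    event_probs:
      acute_gu:
        family: beta
        mean: 0.235139932390302
        se: 0.04702798647806
      acute_gi:
        family: beta
        mean: 0.053347583289724
        se: 0.010669516657945
      late_gu:
        family: beta
        mean: 0.00505910365656
        se: 0.001011820731312
      late_gi:
        family: beta
        mean: 0.007218145074323
        se: 0.001443629014865
      recurrence:
        family: beta
        mean: 0.009445583947003
        se: 0.001889116789401
life_table:
  age:
  - 40
  - 41
  - 42
  - 43
  - 44
  - 45
  - 46
  - 47
  - 48
  - 49
  - 50
  - 51
  - 52
  - 53
  - 54
  - 55
  - 56
  - 57
  - 58
  - 59
  - 60
  - 61
  - 62
  - 63
  - 64
  - 65
  - 66
  - 67
  - 68
  - 69
  - 70
  - 71
  - 72
  - 73
  - 74
  - 75
  - 76
  - 77
  - 78
  - 79
  - 80
  - 81
  - 82
  - 83
  - 84
  - 85
  - 86
  - 87
  - 88
  - 89
  - 90
  - 91
  - 92
  - 93
  - 94
  - 95
  - 96
  - 97
  - 98
  - 99
  - 100
  q_annual:
  - 0.000898923001422
  - 0.000978672813296
  - 0.001065497794549
  - 0.001160025633455
  - 0.00126293970495
  - 0.00137498401099
  - 0.001496968559202
  - 0.001629775218714
  - 0.001774364095496
  - 0.001931780473304
  - 0.002103162370401
  - 0.002289748766693
  - 0.00249288856075
  - 0.002714050321466
  - 0.002954832904858
  - 0.003216977012761
  - 0.00350237777697
  - 0.003813098459812
  - 0.004151385370199
  - 0.004519684102978
  - 0.004920657218997
  - 0.005357203493695
  - 0.005832478873362
  - 0.006349919290587
  - 0.006913265503819
  - 0.007526590140625
  - 0.008194327140143
  - 0.008921303807583
  - 0.009712775712517
  - 0.010574464683231
  - 0.011512600171833
  - 0.01253396428915
  - 0.013645940834986
  - 0.014856568678206
  - 0.016174599872539
  - 0.017609562928251
  - 0.019171831697087
  - 0.020872700368488
  - 0.022724465119254
  - 0.024740513006925
  - 0.026935418749513
  - 0.029325050091262
  - 0.031926682516143
  - 0.034759124138386
  - 0.037842851672949
  - 0.041200158468876
  - 0.044855315675744
  - 0.048834747708326
  - 0.053167223277965
  - 0.057884063371685
  - 0.063019367682605
  - 0.068610261128594
  - 0.074697162241334
  - 0.081324075366079
  - 0.088538908784518
  - 0.096393821060557
  - 0.1049455981129
  - 0.114256063740386
  - 0.124392526567938
  - 0.135428266644248
  - 0.147443065208974
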