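{
 "synthetic": true,
 "note": "synthetic MIST-style node-order manifest: 122 placeholder region labels in ascending atlas index plus the global grey-matter node last; replace labels with a real atlas manifest for real data",
 "labels": [
  "MIST_001",
  "MIST_002",
  "MIST_003",
  "MIST_004",
  "MIST_005",
  "MIST_006",
  "MIST_007",
  "MIST_008",
  "MIST_009",
  "MIST_010",
  "MIST_011",
  "MIST_012",
  "MIST_013",
  "MIST_014",
  "MIST_015",
  "MIST_016",
  "MIST_017",
  "MIST_018",
  "MIST_019",
  "MIST_020",
  "MIST_021",
  "MIST_022",
  "MIST_023",
  "MIST_024",
  "MIST_025",
  "MIST_026",
  "MIST_027",
  "MIST_028",
  "MIST_029",
  "MIST_030",
  "MIST_031",
  "MIST_032",
  "MIST_033",
  "MIST_034",
  "MIST_035",
  "MIST_036",
  "MIST_037",
  "MIST_038",
  "MIST_039",
  "MIST_040",
  "MIST_041",
  "MIST_042",
  "MIST_043",
  "MIST_044",
  "MIST_045",
  "MIST_046",
  "MIST_047",
  "MIST_048",
  "MIST_049",
  "MIST_050",
  "MIST_051",
  "MIST_052",
  "MIST_053",
  "MIST_054",
  "MIST_055",
  "MIST_056",
  "MIST_057",
  "MIST_058",
  "MIST_059",
  "MIST_060",
  "MIST_061",
  "MIST_062",
  "MIST_063",
  "MIST_064",
  "MIST_065",
  "MIST_066",
  "MIST_067",
  "MIST_068",
  "MIST_069",
  "MIST_070",
  "MIST_071",
  "MIST_072",
  "MIST_073",
  "MIST_074",
  "MIST_075",
  "MIST_076",
  "MIST_077",
  "MIST_078",
  "MIST_079",
  "MIST_080",
  "MIST_081",
  "MIST_082",
  "MIST_083",
  "MIST_084",
  "MIST_085",
  "MIST_086",
  "MIST_087",
  "MIST_088",
  "MIST_089",
  "MIST_090",
  "MIST_091",
  "MIST_092",
  "MIST_093",
  "MIST_094",
  "MIST_095",
  "MIST_096",
  "MIST_097",
  "MIST_098",
  "MIST_099",
  "MIST_100",
  "MIST_101",
  "MIST_102",
  "MIST_103",
  "MIST_104",
  "MIST_105",
  "MIST_106",
  "MIST_107",
  "MIST_108",
  "MIST_109",
  "MIST_110",
  "MIST_111",
  "MIST_112",
  "MIST_113",
  "MIST_114",
  "MIST_115",
  "MIST_116",
  "MIST_117",
  "MIST_118",
  "MIST_119",
  "MIST_120",
  "MIST_121",
  "MIST_122",
  "mean GM"
 ]
}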