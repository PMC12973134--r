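{
 "description": "synthetic 30-reaction toy gene-protein-reaction model",
 "reactions": [
  {
   "id": "R000",
   "rule": "g0_0 and (g0_1 or g0_2)",
   "subsystem": "glycolysis"
  },
  {
   "id": "R001",
   "rule": "g1_0 and g1_1",
   "subsystem": "oxphos"
  },
  {
   "id": "R002",
   "rule": "(g2_0 and g2_1) or (g2_2 and g2_3)",
   "subsystem": "fatty_acid_oxidation"
  },
  {
   "id": "R003",
   "rule": "g3_0",
   "subsystem": "nucleotide_conversion"
  },
  {
   "id": "R004",
   "rule": "g4_0",
   "subsystem": "ecm_synthesis"
  },
  {
   "id": "R005",
   "rule": "g5_0",
   "subsystem": "purine_catabolism"
  },
  {
   "id": "R006",
   "rule": "g6_0 and (g6_1 or g6_2)",
   "subsystem": "glycolysis"
  },
  {
   "id": "R007",
   "rule": "g7_0",
   "subsystem": "oxphos"
  },
  {
   "id": "R008",
   "rule": "g8_0 or g8_1",
   "subsystem": "fatty_acid_oxidation"
  },
  {
   "id": "R009",
   "rule": "g9_0",
   "subsystem": "nucleotide_conversion"
  },
  {
   "id": "R010",
   "rule": "g10_0",
   "subsystem": "ecm_synthesis"
  },
  {
   "id": "R011",
   "rule": "(g11_0 and g11_1) or (g11_2 and g11_3)",
   "subsystem": "purine_catabolism"
  },
  {
   "id": "R012",
   "rule": "(g12_0 and g12_1) or (g12_2 and g12_3)",
   "subsystem": "glycolysis"
  },
  {
   "id": "R013",
   "rule": "g13_0",
   "subsystem": "oxphos"
  },
  {
   "id": "R014",
   "rule": "g14_0 or g14_1",
   "subsystem": "fatty_acid_oxidation"
  },
  {
   "id": "R015",
   "rule": "g15_0",
   "subsystem": "nucleotide_conversion"
  },
  {
   "id": "R016",
   "rule": "(g16_0 and g16_1) or (g16_2 and g16_3)",
   "subsystem": "ecm_synthesis"
  },
  {
   "id": "R017",
   "rule": "g17_0",
   "subsystem": "purine_catabolism"
  },
  {
   "id": "R018",
   "rule": "g18_0",
   "subsystem": "glycolysis"
  },
  {
   "id": "R019",
   "rule": "g19_0 and g19_1",
   "subsystem": "oxphos"
  },
  {
   "id": "R020",
   "rule": "g20_0",
   "subsystem": "fatty_acid_oxidation"
  },
  {
   "id": "R021",
   "rule": "(g21_0 and g21_1) or (g21_2 and g21_3)",
   "subsystem": "nucleotide_conversion"
  },
  {
   "id": "R022",
   "rule": "g22_0",
   "subsystem": "ecm_synthesis"
  },
  {
   "id": "R023",
   "rule": "g23_0 and g23_1",
   "subsystem": "purine_catabolism"
  },
  {
   "id": "R024",
   "rule": "g24_0",
   "subsystem": "glycolysis"
  },
  {
   "id": "R025",
   "rule": "g25_0 and g25_1",
   "subsystem": "oxphos"
  },
  {
   "id": "R026",
   "rule": "g26_0 and (g26_1 or g26_2)",
   "subsystem": "fatty_acid_oxidation"
  },
  {
   "id": "R027",
   "rule": "(g27_0 and g27_1) or (g27_2 and g27_3)",
   "subsystem": "nucleotide_conversion"
  },
  {
   "id": "R028",
   "rule": "g28_0 or g28_1",
   "subsystem": "ecm_synthesis"
  },
  {
   "id": "R029",
   "rule": "g29_0",
   "subsystem": "purine_catabolism"
  }
 ]
}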