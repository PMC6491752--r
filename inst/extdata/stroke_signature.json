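{
  "stroke_enriched": [
    "Butyricimonas",
    "Parabacteroides",
    "Un Rikenellaceae",
    "Un Ruminococcaceae",
    "Oscillospira",
    "Bilophila",
    "Un Enterobacteriaceae"
  ],
  "control_enriched": [
    "Knoellia",
    "Prevotella",
    "Un Clostridiaceae",
    "Coprococcus",
    "Lachnospira",
    "Roseburia",
    "Fecalibacterium",
    "Un Erysipelotrichaceae",
    "Un Caulobacteraceae",
    "Un Bradyrhizobiaceae",
    "Haemophilus"
  ],
  "threshold": 0.1,
  "provenance": "104 stroke vs 90 control training cohort, Wilcoxon rank-sum + BH, FDR < 0.1"
}
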