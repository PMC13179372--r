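[
  {
    "phrases": [
      "mixed",
      "combined"
    ],
    "match": "any",
    "target": "mixed"
  },
  {
    "phrases": [
      "metabolic acidosis",
      "respiratory acidosis"
    ],
    "match": "all",
    "target": "mixed"
  },
  {
    "phrases": [
      "metabolic acidosis",
      "respiratory alkalosis"
    ],
    "match": "all",
    "target": "mixed"
  },
  {
    "phrases": [
      "metabolic alkalosis",
      "respiratory acidosis"
    ],
    "match": "all",
    "target": "mixed"
  },
  {
    "phrases": [
      "metabolic alkalosis",
      "respiratory alkalosis"
    ],
    "match": "all",
    "target": "mixed"
  },
  {
    "phrases": [
      "metabolic acidosis"
    ],
    "match": "any",
    "target": "metabolic_acidosis"
  },
  {
    "phrases": [
      "metabolic alkalosis"
    ],
    "match": "any",
    "target": "metabolic_alkalosis"
  },
  {
    "phrases": [
      "respiratory acidosis"
    ],
    "match": "any",
    "target": "respiratory_acidosis"
  },
  {
    "phrases": [
      "respiratory alkalosis"
    ],
    "match": "any",
    "target": "respiratory_alkalosis"
  },
  {
    "phrases": [
      "normal",
      "no acid-base disturbance"
    ],
    "match": "any",
    "target": "normal"
  }
]
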