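[
  {
    "id": 1,
    "rule": "(Q1 | Q2) & Q3 & any(Q3A, Q3B, Q4, Q5)",
    "description": "Diagnosis by any healthcare provider (Q1 or Q2), round areas of hair loss on face/scalp (Q3), and any supporting feature from Q3A-Q5.",
    "source_confidence": "text_verified"
  },
  {
    "id": 2,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  },
  {
    "id": 3,
    "rule": "(Q1 | Q2) & Q3 & Q3A & any(Q3B, Q4, Q5)",
    "description": "Diagnosis by any healthcare provider (Q1 or Q2), round areas of hair loss (Q3), hair regrowth (Q3A), and any feature from Q3B-Q5.",
    "source_confidence": "text_verified"
  },
  {
    "id": 4,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  },
  {
    "id": 5,
    "rule": "Q3 & any(Q3A, Q3B, Q4, Q5)",
    "description": "Round areas of hair loss on face/scalp (Q3) and any supporting feature from Q3A-Q5; no prior-diagnosis requirement.",
    "source_confidence": "text_verified"
  },
  {
    "id": 6,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  },
  {
    "id": 7,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  },
  {
    "id": 8,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  },
  {
    "id": 9,
    "rule": null,
    "description": "Published only in figure form; not transcribed.",
    "source_confidence": "figure_transcribed"
  }
]
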