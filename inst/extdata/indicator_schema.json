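{
  "indicators": [
    {
      "name": "Crown condition of second molar",
      "abbreviation": "SMC",
      "levels": ["Prothesis", "Distal tooth defect or filling", "Other situations"],
      "proportions": [0.003, 0.096, 0.900]
    },
    {
      "name": "Second molar looseness",
      "abbreviation": "Stability",
      "levels": ["Loose", "Not loose"],
      "proportions": [0.050, 0.949]
    },
    {
      "name": "Relationship of M3M and IAN",
      "abbreviation": "IAN",
      "levels": ["Uncontacted", "Overlap", "Intrude"],
      "proportions": [0.673, 0.101, 0.222]
    },
    {
      "name": "Impacted type (Winter classification)",
      "abbreviation": "Angle",
      "levels": ["Distal", "Vertical and mesial (above contour point)", "Mesial (below contour point)", "Horizontal", "Inverted", "Buccal", "Lingual"],
      "proportions": [0.082, 0.266, 0.263, 0.343, 0.004, 0.012, 0.024]
    },
    {
      "name": "Depth (Pell and Gregory classification)",
      "abbreviation": "Depth",
      "levels": ["High", "Medium", "Low"],
      "proportions": [0.493, 0.445, 0.058]
    },
    {
      "name": "Crown condition of M3M",
      "abbreviation": "Crown",
      "levels": ["Tooth defect (non-mesial defect more than 1/2)", "Unbroken or small decay"],
      "proportions": [0.079, 0.917]
    },
    {
      "name": "Root number",
      "abbreviation": "Roots",
      "levels": ["Two", "Three or more", "One or fusion"],
      "proportions": [0.525, 0.021, 0.450]
    },
    {
      "name": "Root morphology",
      "abbreviation": "Morphology",
      "levels": ["Complete development", "Incomplete development", "Bending in opposite direction or to mesial", "Bending in two or more different directions", "Enlargement in apical site"],
      "proportions": [0.038, 0.072, 0.014, 0.021, 0.849]
    },
    {
      "name": "Root width (cervical vs maximum root width)",
      "abbreviation": "Width",
      "levels": ["a>b or a~b", "a<b"],
      "proportions": [0.840, 0.157]
    },
    {
      "name": "Crown resistance",
      "abbreviation": "Resistance",
      "levels": ["Complete eruption", "Soft tissue coverage", "Partial bone coverage", "Complete bone coverage"],
      "proportions": [0.089, 0.491, 0.404, 0.012]
    },
    {
      "name": "Age",
      "abbreviation": "Age",
      "levels": ["0-25", "25-35", ">35"],
      "proportions": [0.302, 0.547, 0.147]
    },
    {
      "name": "Mouth opening",
      "abbreviation": "Opening",
      "levels": ["Normal", "Limited mouth opening"],
      "proportions": [0.985, 0.012]
    },
    {
      "name": "BMI",
      "abbreviation": "BMI",
      "levels": ["<18.5", "18.5-25", "25-30", "30-35", ">35"],
      "proportions": [0.114, 0.696, 0.150, 0.033, 0.004]
    },
    {
      "name": "Gender",
      "abbreviation": "Gender",
      "levels": ["Male", "Female"],
      "proportions": [0.405, 0.594]
    }
  ]
}
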