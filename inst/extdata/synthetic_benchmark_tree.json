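{
  "comment": "Synthetic three-level benchmark hierarchy used by the packaged simulation benchmark: 4 major, 7 minor, 10 leaf types. Entirely synthetic; types are named for the tissue roles they mimic.",
  "roots": [
    {
      "name": "Epithelial-like",
      "children": [
        {
          "name": "Luminal-like",
          "children": [
            {"name": "Luminal A-like"},
            {"name": "Luminal B-like"}
          ]
        },
        {"name": "Basal-like"}
      ]
    },
    {
      "name": "Immune-like",
      "children": [
        {
          "name": "T-like",
          "children": [
            {"name": "CD4-like"},
            {"name": "CD8-like"}
          ]
        },
        {"name": "B-like"}
      ]
    },
    {
      "name": "Stromal-like",
      "children": [
        {
          "name": "Fibroblast-like",
          "children": [
            {"name": "Fibro-1"},
            {"name": "Fibro-2"}
          ]
        },
        {"name": "Endothelial-like"}
      ]
    },
    {"name": "Rare-like"}
  ],
  "levels": [
    {
      "name": "major",
      "nodes": ["Epithelial-like", "Immune-like", "Stromal-like", "Rare-like"]
    },
    {
      "name": "minor",
      "nodes": ["Luminal-like", "Basal-like", "T-like", "B-like",
                "Fibroblast-like", "Endothelial-like", "Rare-like"]
    },
    {
      "name": "leaf",
      "nodes": ["Luminal A-like", "Luminal B-like", "Basal-like",
                "CD4-like", "CD8-like", "B-like",
                "Fibro-1", "Fibro-2", "Endothelial-like", "Rare-like"]
    }
  ]
}
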