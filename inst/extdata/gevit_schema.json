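{
  "schema": "gevit-typology",
  "version": 1,
  "chart_classes": ["Common Statistical", "Color", "Relational", "Temporal",
                    "Spatial", "Tree", "Genomic", "Other"],
  "chart_types": [
    {"name": "bar chart", "class": "Common Statistical", "parent": null},
    {"name": "epidemic curve", "class": "Common Statistical", "parent": "bar chart"},
    {"name": "line chart", "class": "Common Statistical", "parent": null},
    {"name": "scatter chart", "class": "Common Statistical", "parent": null},
    {"name": "pie chart", "class": "Common Statistical", "parent": null},
    {"name": "heatmap", "class": "Color", "parent": null},
    {"name": "node-link graph", "class": "Relational", "parent": null},
    {"name": "geographic map", "class": "Spatial", "parent": null},
    {"name": "phylogenetic tree", "class": "Tree", "parent": null},
    {"name": "dendrogram", "class": "Tree", "parent": null},
    {"name": "genomic map", "class": "Genomic", "parent": null},
    {"name": "table", "class": "Other", "parent": null},
    {"name": "image", "class": "Other", "parent": null},
    {"name": "gel image", "class": "Other", "parent": "image"}
  ],
  "combination_types": ["Single", "Composite", "Small Multiples",
                        "Many Types Linked", "Many Types General",
                        "Complex Combination"],
  "mark_kinds": ["point", "line", "area", "text", "connection",
                 "containment", "glyph"],
  "glyph_types": ["pie chart"],
  "aesthetics": ["size", "shape", "color", "texture"],
  "enhancement_modes": ["add-marks", "re-encode-marks"],
  "enhancement_structure": ["structured", "annotation"]
}
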