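{
  "relations": [
    {"id": 1,  "name_zh": "含有",   "name_en": "Contains",          "abbrev": "CO"},
    {"id": 2,  "name_zh": "别名",   "name_en": "Another name",      "abbrev": "AN"},
    {"id": 3,  "name_zh": "属于",   "name_en": "Belong",            "abbrev": "BE"},
    {"id": 4,  "name_zh": "查处",   "name_en": "Investigation",     "abbrev": "IN"},
    {"id": 5,  "name_zh": "功效",   "name_en": "Efficacy",          "abbrev": "EF"},
    {"id": 6,  "name_zh": "不符合", "name_en": "Noncompliance",     "abbrev": "NC"},
    {"id": 7,  "name_zh": "是为",   "name_en": "Is",                "abbrev": "IS"},
    {"id": 8,  "name_zh": "检出",   "name_en": "Detection",         "abbrev": "DE"},
    {"id": 9,  "name_zh": "污染物", "name_en": "Contaminants",      "abbrev": "CT"},
    {"id": 10, "name_zh": "食品类别", "name_en": "Food category",   "abbrev": "FC"},
    {"id": 11, "name_zh": "不良反应", "name_en": "Adverse reactions", "abbrev": "AR"},
    {"id": 12, "name_zh": "无关",   "name_en": "Other",             "abbrev": "O"}
  ]
}
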