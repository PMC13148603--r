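{
  "version": "1.0",
  "notes": "Default unified ordinal scales for urinalysis components. Dipstick chemistries use 4 levels (negative, trace/1+, moderate/2+, large/>=3+); microscopy counts use 4 binned levels (none, few 0-10/hpf, moderate 11-50/hpf, many >50/hpf); nitrite is binary. Within each dialect the vocabulary is declared in nondecreasing level order and the first entry per level is the canonical rendering. Site-specific maps may override this file.",
  "components": {
    "blood": {
      "kind": "dipstick",
      "levels": ["negative", "trace_1plus", "moderate_2plus", "large_3plus"],
      "dialects": {
        "qualitative": {"negative": 0, "trace": 1, "small": 1, "moderate": 2, "large": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"negative": 0, "10 ery/ul": 1, "50 ery/ul": 2, "250 ery/ul": 3}
      }
    },
    "glucose": {
      "kind": "dipstick",
      "levels": ["negative", "trace_1plus", "moderate_2plus", "large_3plus"],
      "dialects": {
        "qualitative": {"negative": 0, "trace": 1, "small": 1, "moderate": 2, "large": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"negative": 0, "100 mg/dl": 1, "250 mg/dl": 2, "500 mg/dl": 3, "1000 mg/dl": 3}
      }
    },
    "ketones": {
      "kind": "dipstick",
      "levels": ["negative", "trace_1plus", "moderate_2plus", "large_3plus"],
      "dialects": {
        "qualitative": {"negative": 0, "trace": 1, "small": 1, "moderate": 2, "large": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"negative": 0, "15 mg/dl": 1, "40 mg/dl": 2, "80 mg/dl": 3, "160 mg/dl": 3}
      }
    },
    "leukocyte_esterase": {
      "kind": "dipstick",
      "levels": ["negative", "trace_1plus", "moderate_2plus", "large_3plus"],
      "dialects": {
        "qualitative": {"negative": 0, "trace": 1, "small": 1, "moderate": 2, "large": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"negative": 0, "15 leu/ul": 1, "70 leu/ul": 2, "125 leu/ul": 3, "500 leu/ul": 3}
      }
    },
    "nitrites": {
      "kind": "binary",
      "levels": ["negative", "positive"],
      "dialects": {
        "qualitative": {"negative": 0, "positive": 1},
        "semiquantitative": {"negative": 0, "positive": 1, "1+": 1},
        "quantitative": {"negative": 0, "positive": 1}
      }
    },
    "protein": {
      "kind": "dipstick",
      "levels": ["negative", "trace_1plus", "moderate_2plus", "large_3plus"],
      "dialects": {
        "qualitative": {"negative": 0, "trace": 1, "small": 1, "moderate": 2, "large": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"negative": 0, "30 mg/dl": 1, "100 mg/dl": 2, "300 mg/dl": 3, "500 mg/dl": 3}
      }
    },
    "bacteria": {
      "kind": "microscopy",
      "levels": ["none", "few_0_10", "moderate_11_50", "many_gt50"],
      "dialects": {
        "qualitative": {"none": 0, "rare": 1, "few": 1, "moderate": 2, "many": 3, "loaded": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"0/hpf": 0, "2-10/hpf": 1, "11-50/hpf": 2, ">50/hpf": 3}
      }
    },
    "epithelial_cells": {
      "kind": "microscopy",
      "levels": ["none", "few_0_10", "moderate_11_50", "many_gt50"],
      "dialects": {
        "qualitative": {"none": 0, "rare": 1, "few": 1, "moderate": 2, "many": 3, "loaded": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"0/hpf": 0, "2-10/hpf": 1, "11-50/hpf": 2, ">50/hpf": 3}
      }
    },
    "white_blood_cells": {
      "kind": "microscopy",
      "levels": ["none", "few_0_10", "moderate_11_50", "many_gt50"],
      "dialects": {
        "qualitative": {"none": 0, "rare": 1, "few": 1, "moderate": 2, "many": 3, "loaded": 3},
        "semiquantitative": {"negative": 0, "1+": 1, "2+": 2, "3+": 3, "4+": 3},
        "quantitative": {"0/hpf": 0, "2-10/hpf": 1, "11-50/hpf": 2, ">50/hpf": 3}
      }
    }
  }
}
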