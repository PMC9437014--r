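{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "metpanel case report",
  "type": "object",
  "required": ["case_id", "status", "findings"],
  "properties": {
    "case_id": {"type": "string"},
    "status": {"enum": ["positive", "unclear", "negative"]},
    "sex": {"enum": ["male", "female", "unknown"]},
    "region": {"type": ["string", "null"]},
    "consanguinity": {"type": ["string", "null"]},
    "family_history": {"type": ["string", "null"]},
    "age_onset_years": {"type": ["number", "null"]},
    "age_testing_years": {"type": ["number", "null"]},
    "syndromic_flag": {"type": "boolean"},
    "qc": {"type": ["string", "null"]},
    "findings": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["variant_key", "gene", "disease_id", "final_class",
                     "genotype_pattern"],
        "properties": {
          "variant_key": {"type": "string"},
          "gene": {"type": "string"},
          "disease_id": {"type": "string"},
          "disease_name": {"type": "string"},
          "type": {"enum": ["snv", "cnv_del", "cnv_dup"]},
          "zygosity": {"enum": ["het", "hom", "hemi"]},
          "base_class": {"enum": ["P", "LP", "VUS", "LB", "B"]},
          "final_class": {"enum": ["P", "LP", "VUS", "LB", "B"]},
          "evidence": {"type": "string"},
          "genotype_pattern": {"type": "string"},
          "phase": {"enum": ["cis", "trans_supported", "unknown"]},
          "treatable": {"type": "boolean"},
          "outcome": {"enum": ["positive", "unclear", "carrier", "none"]}
        }
      }
    },
    "excluded": {"type": "array"},
    "biochem_summary": {
      "type": "array",
      "items": {
        "type": "object",
        "properties": {
          "assay_id": {"type": "string"},
          "value": {"type": "number"},
          "call": {"enum": ["pathologic", "normal", "borderline"]}
        }
      }
    },
    "recommendations": {
      "type": "array",
      "items": {"enum": ["parental_testing", "biomarker_followup"]}
    }
  }
}
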