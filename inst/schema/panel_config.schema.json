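{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "metpanel panel configuration",
  "type": "object",
  "required": ["genes"],
  "properties": {
    "panel": {"type": "object"},
    "thresholds": {
      "type": "object",
      "properties": {
        "maf_snv": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "maf_cnv": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "splice_score_min": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "het_cnv_min_exons": {"type": "integer", "minimum": 1},
        "qc_min_coverage_fraction": {"type": "number", "exclusiveMinimum": 0, "maximum": 1},
        "qc_min_depth": {"type": "integer", "minimum": 1},
        "healthy_cohort_size": {"type": "integer", "minimum": 1}
      }
    },
    "assays": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["assay_id", "kind", "analyte", "pathologic_direction",
                     "reference_low", "reference_high", "units"],
        "properties": {
          "assay_id": {"type": "string"},
          "kind": {"enum": ["enzyme_activity", "biomarker"]},
          "analyte": {"type": "string"},
          "pathologic_direction": {"enum": ["below_range", "above_range"]},
          "reference_low": {"type": "number"},
          "reference_high": {"type": "number"},
          "units": {"type": "string"}
        }
      }
    },
    "genes": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["symbol", "exon_count", "inheritance", "disease_id",
                     "disease_name", "category"],
        "properties": {
          "symbol": {"type": "string"},
          "transcript": {"type": "string"},
          "exon_count": {"type": "integer", "minimum": 1},
          "inheritance": {"enum": ["AR", "AD", "XL"]},
          "disease_id": {"type": "string"},
          "disease_name": {"type": "string"},
          "category": {"type": "string"},
          "treatable": {"type": "boolean"},
          "assays": {"type": "array", "items": {"type": "string"}},
          "female_het_reportable": {"type": "boolean"},
          "lof_mechanism": {"type": "boolean"},
          "placeholder": {"type": "boolean"}
        }
      }
    }
  }
}
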