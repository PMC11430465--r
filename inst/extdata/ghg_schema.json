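{
  "format": "UTF-8 delimited text, comma-separated with quoted fields (canonical); tab-separated accepted on read",
  "tables": {
    "sources": {
      "file": "sources.csv",
      "columns": {
        "source_id": {"type": "string", "unique": true},
        "citation": {"type": "string"},
        "year_published": {"type": "integer"}
      }
    },
    "sites": {
      "file": "sites.csv",
      "columns": {
        "site_id": {"type": "string", "unique": true},
        "source_id": {"type": "string", "references": "sources.source_id"},
        "water_body": {"type": "enum", "values": ["lake", "river"]},
        "zone": {"type": "enum", "values": ["continuous", "discontinuous", "sporadic_isolated", "glacial"]},
        "latitude": {"type": "number", "range": [-90, 90], "unit": "degrees"},
        "longitude": {"type": "number", "range": [-180, 180], "unit": "degrees"}
      }
    },
    "concentrations": {
      "file": "concentrations.csv",
      "note": "schema-validated but never used for emission estimates",
      "columns": {
        "site_id": {"type": "string", "references": "sites.site_id"},
        "date_or_period": {"type": "string", "format": "YYYY-MM-DD | YYYY-MM | month name | season/annual label"},
        "gas": {"type": "enum", "values": ["CO2", "CH4", "N2O"]},
        "concentration": {"type": "number", "unit": "umol L-1"}
      }
    },
    "fluxes": {
      "file": "fluxes.csv",
      "columns": {
        "site_id": {"type": "string", "references": "sites.site_id"},
        "date_or_period": {"type": "string", "format": "YYYY-MM-DD | YYYY-MM | month name | season/annual label"},
        "gas": {"type": "enum", "values": ["CO2", "CH4", "N2O"]},
        "pathway": {"type": "enum", "values": ["diffusive", "ebullitive", "total"], "note": "ebullitive/total only for CH4; ebullitive flux >= 0"},
        "flux": {"type": "number", "unit": "mmol m-2 day-1", "signed": true}
      }
    }
  },
  "area_table": {
    "columns": {
      "zone": {"type": "enum", "values": ["continuous", "discontinuous", "sporadic_isolated", "glacial"]},
      "water_body": {"type": "enum", "values": ["lake", "river"]},
      "month": {"type": "integer", "range": [1, 12]},
      "area_km2": {"type": "number", "range": [0, null], "unit": "km2 open water"}
    }
  }
}
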