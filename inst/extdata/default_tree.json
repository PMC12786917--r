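{
  "predicate": {"source": "SP_COUNT", "comparator": "GT", "threshold": 8.5},
  "no": "NO_EMS",
  "yes": {
    "predicate": {"source": "SUM_VAS", "comparator": "GT", "threshold": 12},
    "no": {
      "predicate": {"source": "ITEM", "item_id": "dysuria", "comparator": "IS_TRUE"},
      "yes": "EMS",
      "no": "NO_EMS"
    },
    "yes": {
      "predicate": {"source": "ITEM", "item_id": "strongest_4wks_nrs", "comparator": "GT", "threshold": 3},
      "no": {
        "predicate": {"source": "ITEM", "item_id": "adj_flashing", "comparator": "IS_TRUE"},
        "yes": "EMS",
        "no": "NO_EMS"
      },
      "yes": {
        "predicate": {"source": "ITEM", "item_id": "adj_cramping", "comparator": "IS_TRUE"},
        "yes": "EMS",
        "no": {
          "predicate": {"source": "ITEM", "item_id": "adj_pulling", "comparator": "IS_TRUE"},
          "yes": "EMS",
          "no": {
            "predicate": {"source": "ITEM", "item_id": "dyspareunia", "comparator": "IS_TRUE"},
            "yes": "EMS",
            "no": {
              "predicate": {"source": "ITEM", "item_id": "obstipation", "comparator": "IS_TRUE"},
              "yes": "EMS",
              "no": {
                "predicate": {"source": "ITEM", "item_id": "loc_thighs_legs", "comparator": "IS_TRUE"},
                "yes": "EMS",
                "no": {
                  "predicate": {"source": "ITEM", "item_id": "loc_vagina_mons", "comparator": "IS_TRUE"},
                  "yes": "EMS",
                  "no": "NO_EMS"
                }
              }
            }
          }
        }
      }
    }
  }
}
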