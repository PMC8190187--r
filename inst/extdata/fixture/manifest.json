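{
  "seed": 42,
  "samples": ["NPC", "D2", "D5", "iPSC", "ESC"],
  "reference": "NPC",
  "endpoints": ["iPSC", "ESC"],
  "funnel": {
    "input": 60,
    "snp_informative": 48,
    "expressed": 36
  },
  "escapees": ["gene009", "gene016", "gene018", "gene036", "gene038", "gene046", "gene049", "gene051"],
  "biallelic_endpoint": ["gene002", "gene004", "gene005", "gene006", "gene007", "gene008", "gene010", "gene011", "gene013", "gene014", "gene015", "gene017", "gene019", "gene020", "gene021", "gene022", "gene023", "gene025", "gene026", "gene027", "gene028", "gene029", "gene031", "gene032", "gene033", "gene034", "gene035", "gene037", "gene039", "gene040", "gene041", "gene043", "gene045", "gene047", "gene048", "gene050", "gene052", "gene054", "gene055", "gene056", "gene057", "gene058", "gene059", "gene060"],
  "reactivation_timepoint": {
    "gene002": 3,
    "gene004": 4,
    "gene005": 3,
    "gene006": 2,
    "gene007": 2,
    "gene008": 3,
    "gene010": 3,
    "gene011": 2,
    "gene013": 3,
    "gene014": 4,
    "gene015": 4,
    "gene017": 3,
    "gene019": 3,
    "gene020": 3,
    "gene021": 3,
    "gene022": 4,
    "gene023": 4,
    "gene025": 3,
    "gene026": 3,
    "gene027": 2,
    "gene028": 3,
    "gene029": 3,
    "gene031": 3,
    "gene032": 4,
    "gene033": 4,
    "gene034": 4,
    "gene035": 2,
    "gene037": 3,
    "gene039": 4,
    "gene040": 2,
    "gene041": 3,
    "gene043": 3,
    "gene045": 2,
    "gene047": 4,
    "gene048": 3,
    "gene050": 4,
    "gene052": 2,
    "gene054": 4,
    "gene055": 4,
    "gene056": 2,
    "gene057": 2,
    "gene058": 2,
    "gene059": 4,
    "gene060": 4
  },
  "fraction_reactivated": {
    "1": {
      "NPC": 0,
      "D2": 0.272727272727273,
      "D5": 0.727272727272727,
      "iPSC": 1,
      "ESC": 1
    },
    "2": {
      "NPC": 0,
      "D2": 0.0909090909090909,
      "D5": 0.818181818181818,
      "iPSC": 1,
      "ESC": 1
    },
    "3": {
      "NPC": 0,
      "D2": 0.222222222222222,
      "D5": 0.555555555555556,
      "iPSC": 1,
      "ESC": 1
    },
    "4": {
      "NPC": 0,
      "D2": 0.2,
      "D5": 0.6,
      "iPSC": 1,
      "ESC": 1
    },
    "5": {
      "NPC": 0,
      "D2": 0.5,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    }
  },
  "relative_differential_peaks": {
    "1": {
      "NPC": 0,
      "D2": 0.25,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    },
    "2": {
      "NPC": 0,
      "D2": 0.25,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    },
    "3": {
      "NPC": 0,
      "D2": 0.25,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    },
    "4": {
      "NPC": 0,
      "D2": 0.25,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    },
    "5": {
      "NPC": 0,
      "D2": 0.25,
      "D5": 0.5,
      "iPSC": 1,
      "ESC": 1
    }
  },
  "promoter_accessibility": {
    "gene001": 0,
    "gene002": 0,
    "gene003": 0,
    "gene004": 0,
    "gene005": 0,
    "gene006": 0,
    "gene007": 0,
    "gene008": 0,
    "gene009": 0,
    "gene010": 0,
    "gene011": 0,
    "gene012": 0,
    "gene013": 0,
    "gene014": 0,
    "gene015": 0,
    "gene016": 0,
    "gene017": 0,
    "gene018": 0,
    "gene019": 0,
    "gene020": 0,
    "gene021": 0,
    "gene022": 0,
    "gene023": 0,
    "gene024": 0,
    "gene025": 0,
    "gene026": 0,
    "gene027": 0,
    "gene028": 0,
    "gene029": 0,
    "gene030": 0,
    "gene031": 0,
    "gene032": 0,
    "gene033": 0,
    "gene034": 0,
    "gene035": 0,
    "gene036": 0,
    "gene037": 0,
    "gene038": 0,
    "gene039": 0,
    "gene040": 0,
    "gene041": 0,
    "gene042": 0,
    "gene043": 0,
    "gene044": 0,
    "gene045": 0,
    "gene046": 0,
    "gene047": 0,
    "gene048": 0,
    "gene049": 0,
    "gene050": 0,
    "gene051": 0,
    "gene052": 0,
    "gene053": 41.607,
    "gene054": 588,
    "gene055": 0,
    "gene056": 0,
    "gene057": 0,
    "gene058": 0,
    "gene059": 0,
    "gene060": 0
  },
  "peak_density": {
    "1": 2.5,
    "2": 2.5,
    "3": 2.5,
    "4": 2.5,
    "5": 2.5
  }
}
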