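{
  "nodes": [
    {
      "id": 1,
      "parent": null,
      "feature": "sbs4",
      "threshold": 0.237717422244499,
      "left": 2,
      "right": 3,
      "depth": 0,
      "n": 300,
      "events": 214,
      "is_leaf": false
    },
    {
      "id": 2,
      "parent": 1,
      "feature": null,
      "threshold": null,
      "left": null,
      "right": null,
      "depth": 1,
      "n": 86,
      "events": 47,
      "is_leaf": true
    },
    {
      "id": 3,
      "parent": 1,
      "feature": "siri",
      "threshold": 1.76614578909936,
      "left": 4,
      "right": 5,
      "depth": 1,
      "n": 214,
      "events": 167,
      "is_leaf": false
    },
    {
      "id": 4,
      "parent": 3,
      "feature": null,
      "threshold": null,
      "left": null,
      "right": null,
      "depth": 2,
      "n": 84,
      "events": 62,
      "is_leaf": true
    },
    {
      "id": 5,
      "parent": 3,
      "feature": null,
      "threshold": null,
      "left": null,
      "right": null,
      "depth": 2,
      "n": 130,
      "events": 105,
      "is_leaf": true
    }
  ],
  "leaf_group": {
    "2": "low",
    "4": "intermediate",
    "5": "high"
  },
  "group_levels": ["low", "intermediate", "high"],
  "features_used": ["sbs4", "siri"],
  "leaf_hr": {
    "2": 1,
    "4": 1.83278613119272,
    "5": 3.93643854511025
  },
  "endpoint": "pfs",
  "smoking_feature": "sbs4"
}
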