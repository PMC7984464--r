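[
  {
    "rank": 1,
    "octant": {
      "cc_third": 1,
      "ap_third": 1,
      "ml_half": 1
    },
    "importance": 3.85
  },
  {
    "rank": 2,
    "octant": {
      "cc_third": 1,
      "ap_third": 1,
      "ml_half": 2
    },
    "importance": 2.695
  },
  {
    "rank": 3,
    "octant": {
      "cc_third": 1,
      "ap_third": 2,
      "ml_half": 1
    },
    "importance": 1.8865
  },
  {
    "rank": 4,
    "octant": {
      "cc_third": 1,
      "ap_third": 2,
      "ml_half": 2
    },
    "importance": 1.32055
  },
  {
    "rank": 5,
    "octant": {
      "cc_third": 1,
      "ap_third": 3,
      "ml_half": 1
    },
    "importance": 0.924385
  },
  {
    "rank": 6,
    "octant": {
      "cc_third": 1,
      "ap_third": 3,
      "ml_half": 2
    },
    "importance": 0.6470695
  },
  {
    "rank": 7,
    "octant": {
      "cc_third": 2,
      "ap_third": 1,
      "ml_half": 1
    },
    "importance": 0.45294865
  },
  {
    "rank": 8,
    "octant": {
      "cc_third": 2,
      "ap_third": 1,
      "ml_half": 2
    },
    "importance": 0.317064055
  },
  {
    "rank": 9,
    "octant": {
      "cc_third": 2,
      "ap_third": 2,
      "ml_half": 1
    },
    "importance": 0.2219448385
  },
  {
    "rank": 10,
    "octant": {
      "cc_third": 2,
      "ap_third": 2,
      "ml_half": 2
    },
    "importance": 0.15536138695
  },
  {
    "rank": 11,
    "octant": {
      "cc_third": 2,
      "ap_third": 3,
      "ml_half": 1
    },
    "importance": 0.108752970865
  },
  {
    "rank": 12,
    "octant": {
      "cc_third": 2,
      "ap_third": 3,
      "ml_half": 2
    },
    "importance": 0.0761270796055
  },
  {
    "rank": 13,
    "octant": {
      "cc_third": 3,
      "ap_third": 1,
      "ml_half": 1
    },
    "importance": 0.05328895572385
  },
  {
    "rank": 14,
    "octant": {
      "cc_third": 3,
      "ap_third": 1,
      "ml_half": 2
    },
    "importance": 0.037302269006695
  },
  {
    "rank": 15,
    "octant": {
      "cc_third": 3,
      "ap_third": 2,
      "ml_half": 1
    },
    "importance": 0.0261115883046865
  },
  {
    "rank": 16,
    "octant": {
      "cc_third": 3,
      "ap_third": 2,
      "ml_half": 2
    },
    "importance": 0.0182781118132805
  },
  {
    "rank": 17,
    "octant": {
      "cc_third": 3,
      "ap_third": 3,
      "ml_half": 1
    },
    "importance": 0.0127946782692964
  },
  {
    "rank": 18,
    "octant": {
      "cc_third": 3,
      "ap_third": 3,
      "ml_half": 2
    },
    "importance": 0.00895627478850746
  }
]
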