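[
  {
    "rank": 1,
    "delta": 0.195318058582513,
    "d50_gy": 18,
    "n": 2
  },
  {
    "rank": 2,
    "delta": 0.136722641007759,
    "d50_gy": 18.75,
    "n": 2
  },
  {
    "rank": 3,
    "delta": 0.0957058487054315,
    "d50_gy": 19.5,
    "n": 2
  },
  {
    "rank": 4,
    "delta": 0.066994094093802,
    "d50_gy": 20.25,
    "n": 2
  },
  {
    "rank": 5,
    "delta": 0.0468958658656614,
    "d50_gy": 21,
    "n": 2
  },
  {
    "rank": 6,
    "delta": 0.032827106105963,
    "d50_gy": 21.75,
    "n": 2
  },
  {
    "rank": 7,
    "delta": 0.0229789742741741,
    "d50_gy": 22.5,
    "n": 2
  },
  {
    "rank": 8,
    "delta": 0.0160852819919219,
    "d50_gy": 23.25,
    "n": 2
  },
  {
    "rank": 9,
    "delta": 0.0112596973943453,
    "d50_gy": 24,
    "n": 2
  },
  {
    "rank": 10,
    "delta": 0.00788178817604171,
    "d50_gy": 24.75,
    "n": 2
  },
  {
    "rank": 11,
    "delta": 0.0055172517232292,
    "d50_gy": 25.5,
    "n": 2
  },
  {
    "rank": 12,
    "delta": 0.00386207620626044,
    "d50_gy": 26.25,
    "n": 2
  },
  {
    "rank": 13,
    "delta": 0.00270345334438231,
    "d50_gy": 27,
    "n": 2
  },
  {
    "rank": 14,
    "delta": 0.00189241734106761,
    "d50_gy": 27.75,
    "n": 2
  },
  {
    "rank": 15,
    "delta": 0.00132469213874733,
    "d50_gy": 28.5,
    "n": 2
  },
  {
    "rank": 16,
    "delta": 0.000927284497123131,
    "d50_gy": 29.25,
    "n": 2
  },
  {
    "rank": 17,
    "delta": 0.000649099147986192,
    "d50_gy": 30,
    "n": 2
  },
  {
    "rank": 18,
    "delta": 0.000454369403590334,
    "d50_gy": 30.75,
    "n": 2
  }
]
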