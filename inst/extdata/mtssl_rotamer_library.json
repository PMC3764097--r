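{
  "version": 1,
  "topology_hash": "d179596d",
  "provenance": {
    "n_enumerated": 60,
    "n_clashing": 30,
    "n_rescued": 24,
    "removed_ids": [9, 10, 29, 30, 45, 46],
    "vdw_scale": 1.1,
    "max_chi_change": 30,
    "tether": 8.5
  },
  "rotamers": [
    {
      "id": 1,
      "chi": [-60, -60, -90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 2,
      "chi": [-60, -60, -90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 3,
      "chi": [-60, -60, -90, -75, -8],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 4,
      "chi": [-60, -60, -90, -75, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm",
      "parent_chi": [-60, -60, -90, -75, 100]
    },
    {
      "id": 5,
      "chi": [-60, -60, -90, 85, 13],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm",
      "parent_chi": [-60, -60, -90, 75, 8]
    },
    {
      "id": 6,
      "chi": [-60, -60, -90, 90, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm",
      "parent_chi": [-60, -60, -90, 75, -100]
    },
    {
      "id": 7,
      "chi": [-60, -60, 90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 8,
      "chi": [-60, -60, 90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 11,
      "chi": [-60, -60, 90, 75, 8],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm"
    },
    {
      "id": 12,
      "chi": [-60, -60, 90, 75, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mm",
      "parent_chi": [-60, -60, 90, 75, -100]
    },
    {
      "id": 13,
      "chi": [-60, 180, -90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 14,
      "chi": [-60, 180, -90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 15,
      "chi": [-60, 180, -90, -75, -8],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 16,
      "chi": [-60, -180, -90, -75, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, -90, -75, 100]
    },
    {
      "id": 17,
      "chi": [-60, -180, -90, 85, 13],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, -90, 75, 8]
    },
    {
      "id": 18,
      "chi": [-60, -180, -90, 90, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, -90, 75, -100]
    },
    {
      "id": 19,
      "chi": [-60, 180, 90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 20,
      "chi": [-60, 180, 90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 21,
      "chi": [-60, -180, 90, -85, -13],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, 90, -75, -8]
    },
    {
      "id": 22,
      "chi": [-60, -180, 90, -90, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, 90, -75, 100]
    },
    {
      "id": 23,
      "chi": [-60, 180, 90, 75, 8],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt"
    },
    {
      "id": 24,
      "chi": [-60, -180, 90, 75, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "mt",
      "parent_chi": [-60, 180, 90, 75, -100]
    },
    {
      "id": 25,
      "chi": [180, 60, -90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 26,
      "chi": [180, 60, -90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 27,
      "chi": [180, 60, -90, -75, -8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 28,
      "chi": [-180, 60, -90, -75, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp",
      "parent_chi": [180, 60, -90, -75, 100]
    },
    {
      "id": 31,
      "chi": [180, 60, 90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 32,
      "chi": [180, 60, 90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 33,
      "chi": [-180, 60, 90, -85, -13],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp",
      "parent_chi": [180, 60, 90, -75, -8]
    },
    {
      "id": 34,
      "chi": [-180, 60, 90, -90, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp",
      "parent_chi": [180, 60, 90, -75, 100]
    },
    {
      "id": 35,
      "chi": [180, 60, 90, 75, 8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp"
    },
    {
      "id": 36,
      "chi": [-180, 60, 90, 75, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tp",
      "parent_chi": [180, 60, 90, 75, -100]
    },
    {
      "id": 37,
      "chi": [180, -60, -90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 38,
      "chi": [180, -60, -90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 39,
      "chi": [180, -60, -90, -75, -8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 40,
      "chi": [-180, -60, -90, -75, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm",
      "parent_chi": [180, -60, -90, -75, 100]
    },
    {
      "id": 41,
      "chi": [-180, -60, -90, 85, 13],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm",
      "parent_chi": [180, -60, -90, 75, 8]
    },
    {
      "id": 42,
      "chi": [-180, -60, -90, 90, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm",
      "parent_chi": [180, -60, -90, 75, -100]
    },
    {
      "id": 43,
      "chi": [180, -60, 90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 44,
      "chi": [180, -60, 90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 47,
      "chi": [180, -60, 90, 75, 8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm"
    },
    {
      "id": 48,
      "chi": [-180, -60, 90, 75, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tm",
      "parent_chi": [180, -60, 90, 75, -100]
    },
    {
      "id": 49,
      "chi": [180, 180, -90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 50,
      "chi": [180, 180, -90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 51,
      "chi": [180, 180, -90, -75, -8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 52,
      "chi": [-180, -180, -90, -75, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, -90, -75, 100]
    },
    {
      "id": 53,
      "chi": [-180, -180, -90, 85, 13],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, -90, 75, 8]
    },
    {
      "id": 54,
      "chi": [-180, -180, -90, 90, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, -90, 75, -100]
    },
    {
      "id": 55,
      "chi": [180, 180, 90, 180, 77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 56,
      "chi": [180, 180, 90, 180, -77],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 57,
      "chi": [-180, -180, 90, -85, -13],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, 90, -75, -8]
    },
    {
      "id": 58,
      "chi": [-180, -180, 90, -90, 80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, 90, -75, 100]
    },
    {
      "id": 59,
      "chi": [180, 180, 90, 75, 8],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt"
    },
    {
      "id": 60,
      "chi": [-180, -180, 90, 75, -80],
      "sd": [15, 15, 10, 10, 10],
      "class": "tt",
      "parent_chi": [180, 180, 90, 75, -100]
    }
  ]
}
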