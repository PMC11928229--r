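[
  {
    "name": "brown",
    "colors": [
      {"label": "pale brown", "srgb": [196, 164, 132]},
      {"label": "light brown", "srgb": [181, 137, 91]},
      {"label": "medium brown", "srgb": [150, 105, 62]},
      {"label": "reddish brown", "srgb": [139, 87, 66]},
      {"label": "chestnut brown", "srgb": [121, 68, 37]},
      {"label": "dark brown", "srgb": [92, 58, 30]},
      {"label": "blackish brown", "srgb": [61, 40, 23]},
      {"label": "grey brown", "srgb": [141, 124, 102]}
    ]
  },
  {
    "name": "yellow-brown",
    "colors": [
      {"label": "straw", "srgb": [228, 207, 146]},
      {"label": "pale yellow-brown", "srgb": [214, 185, 123]},
      {"label": "light yellow-brown", "srgb": [198, 166, 100]},
      {"label": "golden brown", "srgb": [178, 140, 68]},
      {"label": "tawny", "srgb": [160, 120, 52]},
      {"label": "medium yellow-brown", "srgb": [143, 106, 48]},
      {"label": "dark yellow-brown", "srgb": [115, 84, 38]},
      {"label": "dull yellow-brown", "srgb": [131, 108, 70]}
    ]
  },
  {
    "name": "yellow-green",
    "colors": [
      {"label": "pale yellow-green", "srgb": [214, 223, 148]},
      {"label": "light yellow-green", "srgb": [193, 209, 113]},
      {"label": "yellowish green", "srgb": [166, 189, 84]},
      {"label": "medium yellow-green", "srgb": [140, 169, 64]},
      {"label": "olive", "srgb": [121, 140, 50]},
      {"label": "dark yellow-green", "srgb": [95, 114, 41]},
      {"label": "dull yellow-green", "srgb": [128, 138, 84]},
      {"label": "greyish yellow-green", "srgb": [150, 155, 110]}
    ]
  },
  {
    "name": "green",
    "colors": [
      {"label": "pale green", "srgb": [188, 216, 178]},
      {"label": "light green", "srgb": [146, 196, 132]},
      {"label": "medium green", "srgb": [100, 162, 87]},
      {"label": "grass green", "srgb": [76, 145, 61]},
      {"label": "deep green", "srgb": [52, 114, 46]},
      {"label": "dark green", "srgb": [36, 84, 36]},
      {"label": "glaucous green", "srgb": [133, 162, 137]},
      {"label": "greyish green", "srgb": [139, 152, 129]}
    ]
  },
  {
    "name": "red",
    "colors": [
      {"label": "pale red", "srgb": [222, 155, 142]},
      {"label": "light red", "srgb": [207, 114, 96]},
      {"label": "medium red", "srgb": [182, 73, 57]},
      {"label": "brick red", "srgb": [158, 55, 42]},
      {"label": "purplish red", "srgb": [138, 52, 74]},
      {"label": "dark red", "srgb": [110, 38, 30]},
      {"label": "maroon", "srgb": [88, 28, 34]},
      {"label": "reddish tinged", "srgb": [186, 124, 112]}
    ]
  }
]
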