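{
  "description": "Synthetic dorsal-cortex reference atlas for the mesoreach pipeline: a 12-region-per-hemisphere rectangular layout in a 128x128 reference frame, with named skull landmarks. This is a synthetic stand-in layout, not a tracing of a real common-coordinate-framework atlas; region names follow the standard dorsal-cortex nomenclature.",
  "reference_shape": [128, 128],
  "midline_x": 64,
  "hemisphere": {
    "left_x0": 8,
    "width": 48,
    "top_y0": 20,
    "height": 96,
    "ncols": 3,
    "nrows": 4
  },
  "regions": [
    {"name": "M2",     "col": 0, "row": 0},
    {"name": "M1",     "col": 1, "row": 0},
    {"name": "sspm",   "col": 2, "row": 0},
    {"name": "sspn",   "col": 0, "row": 1},
    {"name": "sspfl",  "col": 1, "row": 1},
    {"name": "sspbfd", "col": 2, "row": 1},
    {"name": "sspun",  "col": 0, "row": 2},
    {"name": "ssphl",  "col": 1, "row": 2},
    {"name": "ssptr",  "col": 2, "row": 2},
    {"name": "rspagl", "col": 0, "row": 3},
    {"name": "rspd",   "col": 1, "row": 3},
    {"name": "visp",   "col": 2, "row": 3}
  ],
  "landmarks": {
    "bregma": [64, 44],
    "lambda": [64, 112],
    "midline_anchor": [64, 20],
    "left_anchor": [32, 44]
  }
}
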