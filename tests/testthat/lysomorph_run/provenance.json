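{
  "package": "lysomorph",
  "version": "0.1.0",
  "config": {
    "out_dir": "lysomorph_run",
    "n_per_condition": 20,
    "master_seed": 1,
    "masks_source": "segmented",
    "conditions": {
      "WT": {
        "preset": "wt_like",
        "grid_shape": 96,
        "voxel_size": 0.2,
        "cell_radius": 6.5,
        "nucleus_radius": 3
      },
      "KO": {
        "preset": "ko_like",
        "grid_shape": 96,
        "voxel_size": 0.2,
        "cell_radius": 6.5,
        "nucleus_radius": 3
      }
    },
    "segmentation": [],
    "ranking": null,
    "pairs": null,
    "tsne": {
      "perplexity": 30,
      "seed": 0,
      "max_iter": 1000
    },
    "n_directions": 1280,
    "n_hull_directions": 320
  },
  "config_md5": "eeccc6a557fef377bdba43209b3c397e",
  "master_seed": 1,
  "n_cells": 40,
  "n_failed": 0,
  "timestamp": "2026-09-30 09:44:01"
}
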