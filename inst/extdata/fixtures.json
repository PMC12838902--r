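{
  "source": "Per-residue interaction distance lists and CSP summary values transcribed from the published reference data for the ST8Sia4 inhibitor systems (docked-pose coordinates were not deposited; these printed lists are the only coordinates-free record of the models).",
  "files": {
    "cmp_distances": {
      "file": "cmp_distances.csv",
      "ligand": "CMP",
      "n_rows": 17,
      "reported_total_sites": 17,
      "reported_mean_distance": 4.55,
      "discrepancy": false,
      "notes": "Counts and the printed mean (4.55) are arithmetically consistent with the distance list."
    },
    "lmwh_distances": {
      "file": "lmwh_distances.csv",
      "ligand": "LMWH",
      "n_rows": 22,
      "reported_total_sites_table": 21,
      "reported_total_sites_text": 20,
      "reported_hydrophobic_text": 14,
      "reported_mean_distance": 4.33,
      "recomputed_mean_distance": 4.3136,
      "discrepancy": true,
      "notes": "Internally inconsistent source: the distance list holds 22 entries (2 moderate + 5 weak + 15 hydrophobic) while the printed totals say 21 (table) and 20 (text, with 14 hydrophobic); the printed mean 4.33 does not equal the list mean (~4.31). The published hotspot count for R252 (6) also disagrees with the list (7 entries). LMWH totals are therefore never used as reference values."
    },
    "lfcinb11_distances": {
      "file": "lfcinb11_distances.csv",
      "ligand": "LFcinB11",
      "n_rows": 23,
      "reported_total_sites_table": 23,
      "reported_total_sites_text": 24,
      "reported_mean_distance": 4.23,
      "recomputed_mean_distance": 4.2913,
      "discrepancy": true,
      "notes": "Class counts (3/5/15) and the hotspot (R252, 7 entries) are consistent; the text total (24) and printed mean (4.23, list mean ~4.29) are not."
    },
    "binding_summary": {
      "file": "binding_summary.csv",
      "discrepancy": false,
      "notes": "Docking/CSP binding ranges, hotspot residues with contact counts, and peak combined CSPs per ligand. LFcinB11 concentration is reported as 80uM in one figure and 60uM in another; the 60uM value is carried here, the alternative noted."
    }
  }
}
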