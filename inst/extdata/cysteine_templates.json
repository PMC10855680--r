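{
  "schema": "SRCR cysteine-group templates. Each group lists ordered cysteine slots: 'positions' are nominal residue positions used by the domain generator; 'start_range' bounds the first slot's position; 'gap_ranges' bound the residue spacing between consecutive slots (min,max) for template matching. The six core slots of Group A are shared by all groups; Group B adds two B-specific slots (an internal disulfide-bonded pair), Group C adds the single C1 slot, at a position distinct from both B-specific slots and without an internal disulfide partner. Ranges here are calibrated to the generator's templates and should be re-calibrated for real SRCR data.",
  "groups": {
    "A": {
      "positions": [12, 27, 50, 64, 86, 103],
      "start_range": [8, 16],
      "gap_ranges": [[11, 19], [19, 27], [10, 18], [18, 26], [13, 21]],
      "meta": {
        "n_cysteines": 6,
        "description": "core template; six conserved cysteines"
      }
    },
    "B": {
      "positions": [12, 27, 33, 50, 57, 64, 86, 103],
      "start_range": [8, 16],
      "gap_ranges": [[11, 19], [2, 10], [13, 21], [3, 11], [3, 11], [18, 26], [13, 21]],
      "meta": {
        "n_cysteines": 8,
        "specific_slots": [3, 5],
        "disulfide": "the two B-specific cysteines form an internal disulfide pair (metadata only; no structural computation)"
      }
    },
    "C": {
      "positions": [12, 18, 27, 50, 64, 86, 103],
      "start_range": [8, 16],
      "gap_ranges": [[2, 10], [5, 13], [19, 27], [10, 18], [18, 26], [13, 21]],
      "meta": {
        "n_cysteines": 7,
        "specific_slots": [2],
        "disulfide": "C1 has no internal disulfide partner (metadata only)"
      }
    }
  }
}
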