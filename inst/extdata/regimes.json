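{
  "_comment": "Default synthetic-session regimes. Phases: early = first 60 s, late = remainder. hazard: bout-initiation rate per second per stimulus; meanBout: mean bout duration in seconds. Values are renewal-process settings chosen to mimic the qualitative early/late structure of mouse-like (many short bouts, both stimuli, early) and rat-like (long early bouts of stimulus 1 only) two-choice sessions.",
  "mouse_like": {
    "early": {
      "hazard": {"stim1": 0.05, "stim2": 0.05},
      "meanBout": {"stim1": 3, "stim2": 3}
    },
    "late": {
      "hazard": {"stim1": 0.03, "stim2": 0.015},
      "meanBout": {"stim1": 8, "stim2": 4}
    }
  },
  "rat_like": {
    "early": {
      "hazard": {"stim1": 0.08, "stim2": 0.005},
      "meanBout": {"stim1": 25, "stim2": 3}
    },
    "late": {
      "hazard": {"stim1": 0.02, "stim2": 0.015},
      "meanBout": {"stim1": 12, "stim2": 4}
    }
  },
  "uniform": {
    "early": {
      "hazard": {"stim1": 0.03, "stim2": 0.03},
      "meanBout": {"stim1": 5, "stim2": 5}
    },
    "late": {
      "hazard": {"stim1": 0.03, "stim2": 0.03},
      "meanBout": {"stim1": 5, "stim2": 5}
    }
  }
}
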