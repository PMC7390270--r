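{
  "name": "table1",
  "version": "1.0",
  "tier": "generation",
  "description": "Kinetic constants and initial concentrations of the zero-dimensional thrombin-generation model in motionless plasma. Values annotated 'as printed' are used verbatim; 'resolved' values carry the published value in as_printed together with the package's resolution of a typographic or unit inconsistency; 'calibrated' values were refit once against the published anchors (peak 141.4 nM at platelet count 350e9/L, linear peak-count relation, saturating ETP-count relation).",
  "parameters": {
    "a1": {"value": 1e-05, "unit": "nM^-2 s^-1", "source": "resolved: printed three times with conflicting units; the TF-VIIa-X term is trimolecular, so nM^-2 s^-1"},
    "a2": {"value": 1e-10, "unit": "nM^-1 s^-1", "source": "as printed: X activation by thrombin"},
    "a3": {"value": 3e-07, "unit": "nM^-1 (1e9/L)^-1 s^-1", "source": "calibrated: printed 1.34e-2 gives instantaneous runaway inconsistent with every published anchor; refit to the linear peak-count relation", "as_printed": 0.0134},
    "a4": {"value": 8e-06, "unit": "nM^-1 s^-1", "source": "as printed: Xa inactivation by antithrombin"},
    "b1": {"value": 0.03, "unit": "nM^-1 s^-1", "source": "as printed: prothrombin activation by Xa"},
    "b2": {"value": 2.6388187225e-04, "unit": "nM^-1 s^-1", "source": "calibrated: printed '1.5 x 6.7' with unit nM^-6 s^-1 is not interpretable; value fixed by the published 141.4 nM peak at platelet count 350e9/L", "as_printed": "1.5 x 6.7 nM^-6 s^-1"},
    "k3": {"value": 1.5e-05, "unit": "nM^-1 s^-1", "source": "as printed: prothrombin activation, linear thrombin feedback"},
    "k4": {"value": 8e-06, "unit": "nM^-2 s^-1", "source": "resolved: printed unit nM^-3 s^-1; the quadratic feedback term requires nM^-2 s^-1 (matches the flow-model table)"},
    "k5": {"value": 1e-10, "unit": "nM^-3 s^-1", "source": "as printed: cubic thrombin feedback"},
    "TF": {"value": 5e-04, "unit": "nM", "source": "as printed: tissue factor (the running text mentions 1 pM; the tabulated 0.5 pM is used)"},
    "VIIa": {"value": 10, "unit": "nM", "source": "as printed: factor VIIa"},
    "X0": {"value": 80, "unit": "nM", "source": "as printed: initial factor X"},
    "II0": {"value": 950, "unit": "nM", "source": "as printed: initial prothrombin"},
    "ATIII0": {"value": 3000, "unit": "nM", "source": "as printed: initial antithrombin"},
    "phi0": {"value": 350, "unit": "1e9/L", "source": "package default: platelet count of the published peak-thrombin anchor"}
  }
}
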