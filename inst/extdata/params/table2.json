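{
  "name": "table2",
  "version": "1.0",
  "tier": "flow",
  "description": "Parameters of the spatial thrombus-formation model (advection-diffusion-reaction factors, platelet transport, Stokes-Brinkman flow) and of the reduced one-equation thrombin-wave model derived from it. Values annotated 'as printed' are used verbatim; 'resolved' values carry the published value together with the package's resolution of a typographic or unit inconsistency; 'package decision' marks constants the source leaves open.",
  "parameters": {
    "h": {"value": 0.02, "unit": "mm", "source": "as printed: space step"},
    "dt": {"value": 0.005, "unit": "s", "source": "as printed: time step"},
    "D": {"value": 5e-05, "unit": "mm^2/s", "source": "as printed: blood-factor diffusion"},
    "Dp": {"value": 2.5e-05, "unit": "mm^2/s", "source": "as printed: platelet diffusion"},
    "k1": {"value": 7e-05, "unit": "(1e9/L)^-1 s^-1", "source": "as printed: prothrombin activation by clot platelets (fitted)"},
    "k2": {"value": 7.5e-06, "unit": "nM^-1 s^-1", "source": "as printed: prothrombin activation by IXa/Xa"},
    "k3": {"value": 1.5e-05, "unit": "nM^-1 s^-1", "source": "as printed: linear thrombin feedback (fitted)"},
    "k4": {"value": 8e-06, "unit": "nM^-2 s^-1", "source": "as printed: quadratic thrombin feedback (fitted)"},
    "k5": {"value": 1e-10, "unit": "nM^-3 s^-1", "source": "as printed: cubic thrombin feedback (fitted)"},
    "k6": {"value": 4.817e-06, "unit": "nM^-1 s^-1", "source": "as printed: thrombin inactivation by antithrombin"},
    "k7": {"value": 1e-09, "unit": "(1e9/L)^-1 s^-1", "source": "as printed: IX/X activation by clot platelets (fitted)"},
    "k8": {"value": 5.2173e-05, "unit": "nM^-1 s^-1", "source": "as printed: IX/X activation by thrombin"},
    "k9": {"value": 2.223e-09, "unit": "nM^-1 s^-1", "source": "as printed: IXa/Xa inactivation by antithrombin"},
    "k10": {"value": 0.05, "unit": "s^-1", "source": "as printed: fibrinogen conversion by thrombin"},
    "K10": {"value": 3160, "unit": "nM", "source": "as printed: fibrinogen Michaelis constant"},
    "k11": {"value": 0.1, "unit": "s^-1", "source": "as printed: fibrin polymerization"},
    "k12": {"value": 0.002, "unit": "nM^-1 s^-1", "source": "as printed: platelet activation by thrombin"},
    "k13": {"value": 4e-09, "unit": "(1e9/L)^-1 s^-1", "source": "as printed: platelet activation by clot platelets"},
    "alpha1": {"value": 77000, "unit": "nM mm s^-1 (as printed: nM^-1 s^-1)", "source": "resolved: printed unit is inconsistent with the flux balance of the surface reaction; the numeric value is used as printed in the Robin flux"},
    "beta1": {"value": 0.225, "unit": "nM^-1", "source": "as printed: surface-complex equilibrium constant"},
    "phi_max": {"value": 400, "unit": "1e9/L", "source": "as printed: maximal platelet packing density"},
    "P0": {"value": 1400, "unit": "nM", "source": "as printed: plasma prothrombin"},
    "A0": {"value": 3400, "unit": "nM", "source": "as printed: plasma antithrombin"},
    "B0": {"value": 200, "unit": "nM", "source": "as printed: total factor IX + X"},
    "VII": {"value": 10, "unit": "nM", "source": "as printed: factor VII"},
    "Fg0": {"value": 7000, "unit": "nM", "source": "as printed: plasma fibrinogen"},
    "phi_f0": {"value": 300, "unit": "1e9/L", "source": "as printed: free platelet density of platelet-rich plasma"},
    "phi_c0": {"value": 1, "unit": "1e9/L", "source": "as printed: activated platelets bound to the subendothelium"},
    "rho": {"value": 1.06e-06, "unit": "kg/mm^3", "source": "as printed: plasma density"},
    "nu": {"value": 1.3, "unit": "mm^2/s", "source": "resolved: printed mm^-2 s^-1; kinematic viscosity has unit mm^2/s"},
    "alpha": {"value": 6e-04, "unit": "mm", "source": "as printed: fibrin fiber radius"},
    "a": {"value": 0.0056, "unit": "s/mm", "source": "resolved: printed '5.6 x 1^-3' read as 5.6e-3; thrombin removal by flow per unit shear rate"},
    "Tstar": {"value": 200, "unit": "nM", "source": "as printed: thrombin threshold delimiting occluded regions"},
    "Ba_decay": {"value": 23.0258509299405, "unit": "mm^-1", "source": "package decision: decay length of the stationary IXa/Xa boundary layer, set so the profile falls to 1% of its wall value at 0.2 mm (the injury patch width)"}
  }
}
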