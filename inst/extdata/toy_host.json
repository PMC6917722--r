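{
  "id": "toy_host",
  "version": "1",
  "compartments": {
    "c": "cytosol",
    "e": "extracellular"
  },
  "metabolites": [
    {
      "id": "glc[e]",
      "name": "glucose",
      "compartment": "e"
    },
    {
      "id": "lac[e]",
      "name": "lactate",
      "compartment": "e"
    },
    {
      "id": "ac[e]",
      "name": "acetate",
      "compartment": "e"
    },
    {
      "id": "pyr[e]",
      "name": "pyruvate",
      "compartment": "e"
    },
    {
      "id": "d25[e]",
      "name": "25-hydroxyvitamin D3",
      "compartment": "e"
    },
    {
      "id": "accoa[c]",
      "name": "acetyl-CoA",
      "compartment": "c"
    },
    {
      "id": "dhc7[c]",
      "name": "7-dehydrocholesterol",
      "compartment": "c"
    },
    {
      "id": "d25[c]",
      "name": "25-hydroxyvitamin D3",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "name": "EX_glc",
      "metabolites": {
        "glc[e]": -1
      },
      "lower_bound": -3,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "EX_lac",
      "name": "EX_lac",
      "metabolites": {
        "lac[e]": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "EX_ac",
      "name": "EX_ac",
      "metabolites": {
        "ac[e]": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "EX_pyr",
      "name": "EX_pyr",
      "metabolites": {
        "pyr[e]": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "EX_d25",
      "name": "EX_d25",
      "metabolites": {
        "d25[e]": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Exchange",
      "objective_coefficient": 1
    },
    {
      "id": "LDH",
      "name": "lactate dehydrogenase (lumped)",
      "metabolites": {
        "lac[e]": -1,
        "pyr[e]": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Acetyl-CoA synthesis",
      "objective_coefficient": 0
    },
    {
      "id": "HMGS",
      "name": "acetyl-CoA to 7-DHC (lumped HMG-CoA chain)",
      "metabolites": {
        "accoa[c]": -3,
        "dhc7[c]": 1
      },
      "lower_bound": 0,
      "upper_bound": 5,
      "gene_reaction_rule": "",
      "subsystem": "Cholesterol biosynthesis",
      "objective_coefficient": 0
    },
    {
      "id": "VD3H",
      "name": "7-DHC hydroxylation (lumped)",
      "metabolites": {
        "dhc7[c]": -1,
        "d25[c]": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Vitamin D metabolism",
      "objective_coefficient": 0
    },
    {
      "id": "D25S",
      "name": "25-OH-D3 secretion",
      "metabolites": {
        "d25[e]": 1,
        "d25[c]": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Vitamin D metabolism",
      "objective_coefficient": 0
    },
    {
      "id": "GLYC",
      "name": "GLYC",
      "metabolites": {
        "glc[e]": -1,
        "accoa[c]": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Glycolysis",
      "objective_coefficient": 0
    },
    {
      "id": "PDH",
      "name": "pyruvate decarboxylase route",
      "metabolites": {
        "pyr[e]": -1,
        "accoa[c]": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Acetyl-CoA synthesis",
      "objective_coefficient": 0
    },
    {
      "id": "ACS",
      "name": "acetate activation",
      "metabolites": {
        "ac[e]": -1,
        "accoa[c]": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "subsystem": "Acetyl-CoA synthesis",
      "objective_coefficient": 0
    }
  ],
  "genes": [],
  "annotation": {
    "units": "mmol/gDW/h",
    "family": "toy",
    "cofactors": false
  }
}
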