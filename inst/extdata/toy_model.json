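{
  "id": "toy_chassis",
  "metabolites": [
    {
      "id": "glc_e",
      "name": "glucose (ext)",
      "formula": "C6H12O6",
      "compartment": "e"
    },
    {
      "id": "glcn_e",
      "name": "gluconate (ext)",
      "formula": "C6H12O7",
      "compartment": "e"
    },
    {
      "id": "g6p_c",
      "name": "glucose 6-phosphate",
      "formula": "C6H13O9P",
      "compartment": "c"
    },
    {
      "id": "pep_c",
      "name": "phosphoenolpyruvate",
      "formula": "C3H5O6P",
      "compartment": "c"
    },
    {
      "id": "pyr_c",
      "name": "pyruvate",
      "formula": "C3H4O3",
      "compartment": "c"
    },
    {
      "id": "trp_e",
      "name": "L-tryptophan (ext)",
      "formula": "C11H12N2O2",
      "compartment": "e"
    },
    {
      "id": "trp_c",
      "name": "L-tryptophan",
      "formula": "C11H12N2O2",
      "compartment": "c"
    },
    {
      "id": "h2o_c",
      "name": "water",
      "formula": "H2O",
      "compartment": "c"
    },
    {
      "id": "indole_c",
      "name": "indole",
      "formula": "C8H7N",
      "compartment": "c"
    },
    {
      "id": "indole_e",
      "name": "indole (ext)",
      "formula": "C8H7N",
      "compartment": "e"
    },
    {
      "id": "nh3_c",
      "name": "ammonia",
      "formula": "NH3",
      "compartment": "c"
    }
  ],
  "reactions": [
    {
      "id": "EX_glc",
      "name": "EX_glc",
      "metabolites": {
        "glc_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_glcn",
      "name": "EX_glcn",
      "metabolites": {
        "glcn_e": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "PTS",
      "name": "PTS",
      "metabolites": {
        "glc_e": -1,
        "pep_c": -1,
        "g6p_c": 1,
        "pyr_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "pts",
      "objective_coefficient": 0
    },
    {
      "id": "GNT",
      "name": "GNT",
      "metabolites": {
        "glcn_e": -1,
        "g6p_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "gntP",
      "objective_coefficient": 0
    },
    {
      "id": "GLY",
      "name": "GLY",
      "metabolites": {
        "g6p_c": -1,
        "pep_c": 2
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "gly1",
      "objective_coefficient": 0
    },
    {
      "id": "PYK",
      "name": "pyruvate kinase",
      "metabolites": {
        "pep_c": -1,
        "pyr_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "pyk",
      "objective_coefficient": 0
    },
    {
      "id": "PYRALT",
      "name": "alternative pyruvate producer",
      "metabolites": {
        "pep_c": -1,
        "pyr_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1,
      "gene_reaction_rule": "alt1",
      "objective_coefficient": 0
    },
    {
      "id": "TRPt",
      "name": "TRPt",
      "metabolites": {
        "trp_e": -1,
        "trp_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "aroP",
      "objective_coefficient": 0
    },
    {
      "id": "EX_trp",
      "name": "EX_trp",
      "metabolites": {
        "trp_e": -1
      },
      "lower_bound": -10,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "TNA",
      "name": "tryptophanase",
      "metabolites": {
        "trp_c": -1,
        "h2o_c": -1,
        "indole_c": 1,
        "pyr_c": 1,
        "nh3_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "tna",
      "objective_coefficient": 0
    },
    {
      "id": "INDt",
      "name": "INDt",
      "metabolites": {
        "indole_c": -1,
        "indole_e": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_indole",
      "name": "EX_indole",
      "metabolites": {
        "indole_e": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_pyr",
      "name": "EX_pyr",
      "metabolites": {
        "pyr_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_nh3",
      "name": "EX_nh3",
      "metabolites": {
        "nh3_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "EX_h2o",
      "name": "EX_h2o",
      "metabolites": {
        "h2o_c": -1
      },
      "lower_bound": -1000,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "name": "biomass sink",
      "metabolites": {
        "pyr_c": -1,
        "pep_c": -1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    "alt1",
    "aroP",
    "gly1",
    "gntP",
    "pts",
    "pyk",
    "tna"
  ],
  "objective": "BIOMASS"
}
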