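# Default generalized metabolic flux network.
#
# Species are metabolite pools / physiological readings.  Observable species
# carry a biomarker name (canonical units, see ?biomarker_registry) and a
# population reference level used to form log deviations.  Latent species
# (ROM, Ex.HbA1c, Circulation, Fat-lipids, FFA) are internal pools with no
# direct measurement.  Boundary pools written in flux labels (intake, liver,
# muscle, excretion, erythropoiesis, utilization) are not species: a flux with
# an empty substrate or product list exchanges with the environment.
species:
  - {id: Glucose,     biomarker: fbg,           reference_level: 8.7}
  - {id: Cholesterol, biomarker: total_chol,    reference_level: 4.5}
  - {id: HDL,         biomarker: hdl,           reference_level: 1.2}
  - {id: LDL,         biomarker: ldl,           reference_level: 2.6}
  - {id: TG,          biomarker: tg,            reference_level: 1.5}
  - {id: Creatinine,  biomarker: scr,           reference_level: 74.0}
  - {id: BMI,         biomarker: bmi,           reference_level: 26.8}
  - {id: HbA1c,       biomarker: hba1c,         reference_level: 8.0}
  - {id: Hb,          biomarker: hb,            reference_level: 13.1}
  - {id: SBP,         biomarker: sbp,           reference_level: 133.8}
  - {id: ACR,         biomarker: acr,           reference_level: 1.3}
  - {id: Albumin,     biomarker: serum_albumin, reference_level: 4.0}
  - {id: ALT,         biomarker: alt,           reference_level: 33.4}
  - {id: AST,         biomarker: ast,           reference_level: 34.2}
  - {id: Hct,         biomarker: hematocrit,    reference_level: 39.6}
  - {id: ROM}
  - {id: Ex.HbA1c}
  - {id: Circulation}
  - {id: Fat-lipids}
  - {id: FFA}

# 21 informative fluxes.  Reversible edges are a single signed column of the
# incidence matrix (positive = forward direction as written).
fluxes:
  - {id: "intake → Glucose",       substrates: [],                 products: [Glucose],            reversible: false, pathway_group: glucose metabolism,       informative: true}
  - {id: "Glucose → utilization",  substrates: [Glucose],          products: [],                   reversible: false, pathway_group: glucose metabolism,       informative: true}
  - {id: "Glucose → ROM",          substrates: [Glucose],          products: [ROM],                reversible: false, pathway_group: glucose metabolism,       informative: true}
  - {id: "Hb.ROM → HbA1c",         substrates: [Hb, ROM],          products: [HbA1c],              reversible: false, pathway_group: ROS-HbA1c production,      informative: true}
  - {id: "HbA1c → Ex.HbA1c",       substrates: [HbA1c],            products: [Ex.HbA1c],           reversible: false, pathway_group: ROS-HbA1c production,      informative: true}
  - {id: "Ex.HbA1c → ACR",         substrates: [Ex.HbA1c],         products: [ACR],                reversible: false, pathway_group: ROS-HbA1c production,      informative: true}
  - {id: "erythropoiesis → Hb",    substrates: [],                 products: [Hb],                 reversible: false, pathway_group: respiration-circulation,  informative: true}
  - {id: "Hb ↔ Hct",               substrates: [Hb],               products: [Hct],                reversible: true,  pathway_group: respiration-circulation,  informative: true}
  - {id: "Hb → circulation",       substrates: [Hb],               products: [Circulation],        reversible: false, pathway_group: respiration-circulation,  informative: true}
  - {id: "circulation → SBP",      substrates: [Circulation],      products: [SBP],                reversible: false, pathway_group: blood pressure,           informative: true}
  - {id: "Glucose → Fat-lipids",   substrates: [Glucose],          products: [Fat-lipids],         reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "Fat-lipids ↔ FFA",       substrates: [Fat-lipids],       products: [FFA],                reversible: true,  pathway_group: lipid metabolism,         informative: true}
  - {id: "FFA → BMI",              substrates: [FFA],              products: [BMI],                reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "Fat-lipids → TG",        substrates: [Fat-lipids],       products: [TG],                 reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "TG → LDL",               substrates: [TG],               products: [LDL],                reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "LDL → Cholesterol",      substrates: [LDL],              products: [Cholesterol],        reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "Cholesterol → HDL",      substrates: [Cholesterol],      products: [HDL],                reversible: false, pathway_group: lipid metabolism,         informative: true}
  - {id: "muscle → Creatinine",    substrates: [],                 products: [Creatinine],         reversible: false, pathway_group: kidney-creatinine,        informative: true}
  - {id: "Creatinine → excretion", substrates: [Creatinine, ACR],  products: [],                   reversible: false, pathway_group: kidney-creatinine,        informative: true}
  - {id: "liver → Albumin",        substrates: [],                 products: [Albumin, ALT, AST],  reversible: false, pathway_group: albumin-ACR,              informative: true}
  - {id: "Albumin → ACR",          substrates: [Albumin],          products: [ACR],                reversible: false, pathway_group: albumin-ACR,              informative: true}

# Biomarker input configurations (column sets of the cohort table).
input_sets:
  identification-10: [fbg, total_chol, hdl, ldl, tg, scr, bmi, hba1c, hb, sbp]
  incomplete-11:     [fbg, total_chol, hdl, ldl, tg, scr, bmi, hba1c, hb, sbp, acr]
  complete-14:       [fbg, total_chol, hdl, ldl, tg, scr, bmi, hba1c, hb, sbp, serum_albumin, alt, ast, hematocrit]

informative_count: 21
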