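[
  {"id": "lung", "name": "Lung", "category": "lung tissue findings"},
  {"id": "decreased_translucency", "name": "Decreased translucency", "parent": "lung", "category": "lung tissue findings"},
  {"id": "infiltrate", "name": "Infiltrate", "parent": "decreased_translucency", "category": "lung tissue findings"},
  {"id": "consolidation", "name": "Consolidation", "parent": "infiltrate", "category": "lung tissue findings"},
  {"id": "diffuse_infiltrate", "name": "Diffuse infiltrate", "parent": "infiltrate", "category": "lung tissue findings"},
  {"id": "cavitary_lesion", "name": "Cavitary lesion", "parent": "infiltrate", "category": "lung tissue findings"},
  {"id": "nodule_tumor_or_mass", "name": "Nodule, tumor or mass", "parent": "infiltrate", "category": "lung tissue findings", "reconstructed": true},
  {"id": "atelectasis", "name": "Atelectasis", "category": "lung tissue findings"},
  {"id": "cysts_bullae", "name": "Cysts/bullae", "category": "lung tissue findings"},
  {"id": "increased_interstitial", "name": "Increased interstitial markings", "category": "lung tissue findings"},
  {"id": "pleural_changes", "name": "Pleural changes", "category": "lung tissue findings"},
  {"id": "pleural_calcification", "name": "Pleural calcification", "parent": "pleural_changes", "category": "lung tissue findings"},
  {"id": "pleural_thickening", "name": "Pleural thickening", "parent": "pleural_changes", "category": "lung tissue findings"},
  {"id": "pleural_effusion", "name": "Pleural effusion", "category": "lung tissue findings"},
  {"id": "pneumothorax", "name": "Pneumothorax", "category": "lung tissue findings"},
  {"id": "cardiomediastinum", "name": "Cardiomediastinum", "category": "cardiomediastinal findings"},
  {"id": "cardiomegaly", "name": "Cardiomegaly", "parent": "cardiomediastinum", "category": "cardiomediastinal findings"},
  {"id": "lymph_node_pathology", "name": "Lymph node pathology", "parent": "cardiomediastinum", "category": "cardiomediastinal findings"},
  {"id": "other_cardiomediastinum", "name": "Other cardiomediastinum", "parent": "cardiomediastinum", "category": "cardiomediastinal findings"},
  {"id": "vascular_changes", "name": "Vascular changes", "parent": "cardiomediastinum", "category": "cardiomediastinal findings"},
  {"id": "widening_of_mediastinum", "name": "Widening of mediastinum", "parent": "vascular_changes", "category": "cardiomediastinal findings"},
  {"id": "mediastinal_tumor", "name": "Mediastinal tumor", "parent": "widening_of_mediastinum", "category": "cardiomediastinal findings", "reconstructed": true},
  {"id": "aneurism", "name": "Aneurism", "parent": "vascular_changes", "category": "cardiomediastinal findings"},
  {"id": "stasis_edema", "name": "Stasis/edema", "category": "other findings"},
  {"id": "bone", "name": "Bone", "category": "other findings"},
  {"id": "medical_device_correct_placement", "name": "Medical device, correct placement", "category": "other findings"},
  {"id": "other_non_pathological", "name": "Other non-pathological", "category": "other findings"},
  {"id": "pneumonia_infection", "name": "Pneumonia/infection", "category": "differential diagnosis"}
]
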