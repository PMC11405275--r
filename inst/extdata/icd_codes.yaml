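# ICD code prefixes identifying the four target pathologies. MIMIC-IV
# stores codes without dots; matching is by prefix on the undotted code.
# These are documented reconstructions from the ICD-9/ICD-10 families and
# are replaceable via the icd_codes argument of the builder.
appendicitis:
  icd9: ["540", "541", "542"]
  icd10: ["K35", "K36", "K37"]
cholecystitis:
  icd9: ["5750", "5751", "57510", "57511", "57512", "5740", "5743", "5746"]
  icd10: ["K810", "K811", "K812", "K819", "K8000", "K8001", "K8010", "K8011", "K8040", "K8041", "K8042", "K8043", "K8044", "K8045", "K8046", "K8047"]
diverticulitis:
  icd9: ["56211", "56213"]
  icd10: ["K5720", "K5721", "K5732", "K5733", "K5740", "K5741", "K5752", "K5753", "K5780", "K5781", "K5792", "K5793"]
pancreatitis:
  icd9: ["5770"]
  icd10: ["K85"]
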