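# Accepted alternative phrasings per target pathology. A diagnosis counts
# as correct when its FIRST listed diagnosis contains one of these phrases
# (case-insensitive). Phrasing lists must be disjoint across pathologies.
# A medically incomplete mention (e.g. plain "gallstones" without an
# inflammatory term) deliberately does not match.
appendicitis:
  - appendicitis
  - inflamed appendix
  - inflammation of the appendix
cholecystitis:
  - cholecystitis
  - inflamed gallbladder
  - gallbladder inflammation
  - inflammation of the gallbladder
diverticulitis:
  - diverticulitis
  - inflamed diverticula
  - inflammation of diverticula
pancreatitis:
  - pancreatitis
  - inflamed pancreas
  - inflammation of the pancreas
  - pancreatic inflammation
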