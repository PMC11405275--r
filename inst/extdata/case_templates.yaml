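# Text templates for the synthetic case generator. Placeholders in braces
# are filled per case. Plainly synthetic style on purpose: the generator
# emulates the structure the pipeline consumes, not clinical prose.
# The HPI templates never name the pathology (censoring invariant), and the
# findings use descriptive terms (e.g. "diverticula", never the -itis name)
# so no served observation can leak the gold label.
appendicitis:
  modality: CT
  exam_name: "CT ABDOMEN AND PELVIS W/O CONTRAST"
  hpi: "Patient presents with {duration} days of abdominal pain that began periumbilically and migrated to the right lower quadrant. Associated with anorexia and nausea. Reported fever of {fever} F at home. Pain is {quality} and worsened by movement."
  pe: "Vitals: T {temp} F, HR {hr}, BP 124/78. Abdomen: soft, tender to palpation in the right lower quadrant with guarding at McBurney's point. Rebound tenderness present. Psoas sign positive. Bowel sounds hypoactive."
  findings: "The appendix is dilated to {appendix_mm} mm with wall thickening and periappendiceal fat stranding. No free air. Small amount of free fluid in the pelvis. Remaining bowel loops are normal in caliber."
  findings_complicated: "The appendix is dilated to {appendix_mm} mm with a focal wall defect and an adjacent rim-enhancing fluid collection measuring 3 cm, concerning for perforation with abscess. Periappendiceal fat stranding."
cholecystitis:
  modality: Ultrasound
  exam_name: "US ABDOMEN RUQ"
  hpi: "Patient presents with {duration} days of right upper quadrant pain radiating to the right shoulder, worse after fatty meals. Associated nausea and two episodes of emesis. Reported fever of {fever} F. Pain is {quality}."
  pe: "Vitals: T {temp} F, HR {hr}, BP 131/82. Abdomen: soft, marked tenderness in the right upper quadrant with inspiratory arrest on palpation (Murphy's sign positive). No rebound. Mild scleral icterus."
  findings: "The gallbladder is distended with wall thickening to {gb_wall} mm and pericholecystic fluid. Multiple shadowing gallstones are present. Sonographic Murphy's sign positive. Common bile duct measures {cbd} mm."
  findings_complicated: "The gallbladder is distended with wall thickening to {gb_wall} mm, pericholecystic fluid and a focal wall irregularity concerning for gangrenous change. Multiple shadowing gallstones. Common bile duct measures {cbd} mm."
diverticulitis:
  modality: CT
  exam_name: "CT ABDOMEN AND PELVIS WITH CONTRAST"
  hpi: "Patient presents with {duration} days of left lower quadrant pain, constant and {quality}. Associated with constipation and subjective fever of {fever} F. No hematochezia. Decreased appetite."
  pe: "Vitals: T {temp} F, HR {hr}, BP 138/85. Abdomen: soft, tenderness to palpation in the left lower quadrant with voluntary guarding. No rebound. A mild fullness is palpable in the left lower quadrant. Bowel sounds present."
  findings: "Multiple diverticula of the sigmoid colon with segmental wall thickening over {segment_cm} cm and adjacent pericolonic fat stranding. No free air. No drainable collection."
  findings_complicated: "Multiple diverticula of the sigmoid colon with segmental wall thickening, pericolonic fat stranding and a {abscess_cm} cm adjacent rim-enhancing collection. A few locules of extraluminal gas, concerning for contained perforation."
pancreatitis:
  modality: CT
  exam_name: "CT ABDOMEN W/ CONTRAST"
  hpi: "Patient presents with {duration} days of severe epigastric pain radiating straight through to the back, {quality}, with persistent nausea and vomiting. Symptoms began after a large meal. No fever reported initially, later {fever} F."
  pe: "Vitals: T {temp} F, HR {hr}, BP 118/72. Abdomen: epigastric tenderness with voluntary guarding, no rebound. Hypoactive bowel sounds. No jaundice. Mild abdominal distension."
  findings: "The pancreas is diffusely enlarged and edematous with peripancreatic fat stranding and a small amount of peripancreatic fluid. No necrosis. Gallbladder unremarkable. No biliary ductal dilation."
  findings_complicated: "The pancreas is diffusely enlarged with extensive peripancreatic fat stranding and non-enhancement of approximately {necrosis_pct}% of the gland, consistent with necrosis. Peripancreatic fluid collections are present."
chest_radiograph:
  exam_name: "CHEST X-RAY PA AND LATERAL"
  findings: "The lungs are clear without focal consolidation, effusion or pneumothorax. Cardiomediastinal silhouette within normal limits. No free air under the diaphragm."
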