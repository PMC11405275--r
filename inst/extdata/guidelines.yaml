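# Diagnostic and treatment guideline specification per pathology.
#
# required_lab_categories: diagnostic-workup categories; a category is met
#   when the agent requested at least one member test (directly or via a
#   panel). Membership is an editable reconstruction from standard
#   guideline workups.
# essential_treatments: expected for every correctly diagnosed patient.
# case_specific_treatments: expected only when the patient actually
#   received the corresponding procedure; `procedure_pattern` is a
#   case-insensitive regular expression matched against the patient's
#   procedure records (codes and free text).
# support: supportive care terms. mode `any` = at least one of
#   fluids / pain management / monitoring must be mentioned; mode `all` =
#   all three (supportive care is the mainstay for pancreatitis).
appendicitis:
  required_lab_categories:
    inflammation: [white blood cell count, c-reactive protein]
  essential_treatments:
    antibiotics:
      keywords: [antibiotic, antibiotics, antimicrobial, cephalosporin, ceftriaxone, metronidazole, piperacillin, cefepime, ciprofloxacin]
  case_specific_treatments:
    appendectomy:
      keywords: [appendectomy, appendicectomy, removal of the appendix, removal of appendix]
      procedure_pattern: "appendectomy|appendicectomy|0DTJ|0DBJ|470[019]?"
    drainage:
      keywords: [drain, drainage, percutaneous drain]
      procedure_pattern: "drain|0W9G|549[1]?"
  support:
    mode: any
cholecystitis:
  required_lab_categories:
    inflammation: [white blood cell count, c-reactive protein]
    hepatobiliary: [total bilirubin, direct bilirubin, alkaline phosphatase, aspartate aminotransferase, alanine aminotransferase, gamma glutamyltransferase]
  essential_treatments:
    antibiotics:
      keywords: [antibiotic, antibiotics, antimicrobial, cephalosporin, ceftriaxone, metronidazole, piperacillin, cefepime, ciprofloxacin]
  case_specific_treatments:
    cholecystectomy:
      keywords: [cholecystectomy, removal of the gallbladder, removal of gallbladder, gallbladder removal]
      procedure_pattern: "cholecystectomy|0FT4|0FB4|512[23]?"
    drainage:
      keywords: [drain, drainage, cholecystostomy, percutaneous drain]
      procedure_pattern: "drain|cholecystostomy|0F94|510[12]?"
    ercp:
      keywords: [ercp, endoscopic retrograde cholangiopancreatography]
      procedure_pattern: "ercp|endoscopic retrograde|5110|5184|BF1[01]"
  support:
    mode: any
diverticulitis:
  required_lab_categories:
    inflammation: [white blood cell count, c-reactive protein]
  essential_treatments:
    antibiotics:
      keywords: [antibiotic, antibiotics, antimicrobial, cephalosporin, ceftriaxone, metronidazole, piperacillin, cefepime, ciprofloxacin]
    colonoscopy followup:
      keywords: [colonoscopy, endoscopic follow, interval colonoscopy]
  case_specific_treatments:
    colectomy:
      keywords: [colectomy, sigmoidectomy, bowel resection, resection of the colon, colon resection, hartmann]
      procedure_pattern: "colectomy|sigmoidectomy|hartmann|0DTN|0DBN|457[56]?|458[12]?"
    drainage:
      keywords: [drain, drainage, percutaneous drain]
      procedure_pattern: "drain|0W9G|549[1]?"
  support:
    mode: any
pancreatitis:
  required_lab_categories:
    inflammation: [white blood cell count, c-reactive protein]
    pancreatic enzymes: [lipase, amylase]
    severity: [hematocrit, urea nitrogen, creatinine, calcium, lactate]
  essential_treatments: {}
  case_specific_treatments:
    ercp:
      keywords: [ercp, endoscopic retrograde cholangiopancreatography]
      procedure_pattern: "ercp|endoscopic retrograde|5110|5184|BF1[01]"
    cholecystectomy:
      keywords: [cholecystectomy, removal of the gallbladder, removal of gallbladder, gallbladder removal]
      procedure_pattern: "cholecystectomy|0FT4|0FB4|512[23]?"
    drainage:
      keywords: [drain, drainage, necrosectomy, percutaneous drain]
      procedure_pattern: "drain|necrosectomy|0F9G|529[26]?"
  support:
    mode: all
support_terms:
  fluids: [fluid, fluids, hydration, crystalloid, lactated ringer, normal saline, iv fluids]
  pain management: [pain, analgesia, analgesic, analgesics, morphine, opioid, acetaminophen, paracetamol]
  monitoring: [monitor, monitoring, observation, observe, vitals, vital signs, serial exam]
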