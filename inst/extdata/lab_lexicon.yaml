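# Laboratory test synonym dictionary and panel definitions.
# Canonical names are the keys under `tests`; aliases are matched after
# normalization (lowercase, punctuation stripped, whitespace collapsed).
# This vocabulary is an editable reconstruction seeded from standard
# clinical usage; extend it freely — matching code reloads it at call time.
tests:
  white blood cell count:
    aliases: [wbc, white blood cells, leukocytes, leukocyte count, white count, wbc count]
  hemoglobin:
    aliases: [hgb, hb, haemoglobin]
  hematocrit:
    aliases: [hct, haematocrit, packed cell volume, pcv]
  platelet count:
    aliases: [platelets, plt, thrombocytes, thrombocyte count]
  red blood cell count:
    aliases: [rbc, red blood cells, erythrocytes, erythrocyte count]
  sodium:
    aliases: [na, serum sodium]
  potassium:
    aliases: [k, serum potassium]
  chloride:
    aliases: [cl, serum chloride]
  bicarbonate:
    aliases: [hco3, co2, carbon dioxide, serum bicarbonate]
  urea nitrogen:
    aliases: [bun, blood urea nitrogen, urea]
  creatinine:
    aliases: [cr, serum creatinine, crea]
  glucose:
    aliases: [blood glucose, blood sugar, serum glucose]
  calcium:
    aliases: [ca, serum calcium, total calcium]
  magnesium:
    aliases: [mg, serum magnesium]
  phosphate:
    aliases: [phos, phosphorus, serum phosphate]
  total bilirubin:
    aliases: [bilirubin, tbili, bilirubin total, serum bilirubin]
  direct bilirubin:
    aliases: [dbili, conjugated bilirubin, bilirubin direct]
  alkaline phosphatase:
    aliases: [alp, alk phos]
  aspartate aminotransferase:
    aliases: [ast, sgot, aspartate transaminase]
  alanine aminotransferase:
    aliases: [alt, sgpt, alanine transaminase]
  gamma glutamyltransferase:
    aliases: [ggt, gamma gt, gamma glutamyl transferase]
  albumin:
    aliases: [serum albumin, alb]
  total protein:
    aliases: [protein total, serum protein]
  lipase:
    aliases: [serum lipase]
  amylase:
    aliases: [serum amylase]
  c-reactive protein:
    aliases: [crp, c reactive protein]
  lactate:
    aliases: [lactic acid, serum lactate]
  inr:
    aliases: [international normalized ratio, pt inr, prothrombin time inr]
  ptt:
    aliases: [partial thromboplastin time, aptt, activated partial thromboplastin time]
  urine white blood cells:
    aliases: [urine wbc, urine leukocytes, leukocytes urine]
  urine red blood cells:
    aliases: [urine rbc, urine erythrocytes, hematuria screen]
  urine nitrite:
    aliases: [nitrite, nitrites, urine nitrites]
  urine ketones:
    aliases: [ketones, urine ketone]
panels:
  complete blood count:
    aliases: [cbc, full blood count, fbc, complete blood count with differential, cbc with diff]
    members: [white blood cell count, hemoglobin, hematocrit, platelet count, red blood cell count]
  basic metabolic panel:
    aliases: [bmp, chem 7, chemistry panel, basic metabolic profile, electrolytes, electrolyte panel]
    members: [sodium, potassium, chloride, bicarbonate, urea nitrogen, creatinine, glucose, calcium]
  liver function panel:
    aliases: [lfts, lft, liver function tests, liver panel, hepatic function panel, hepatic panel]
    members: [total bilirubin, direct bilirubin, alkaline phosphatase, aspartate aminotransferase, alanine aminotransferase, albumin, total protein]
  renal function panel:
    aliases: [renal panel, kidney function tests, renal function tests]
    members: [urea nitrogen, creatinine]
  urinalysis:
    aliases: [ua, urine analysis, urine dipstick, urinalysis panel]
    members: [urine white blood cells, urine red blood cells, urine nitrite, urine ketones]
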