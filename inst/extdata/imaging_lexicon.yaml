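# Imaging modality and anatomical-region keyword lists, plus special exam
# names that map straight to a (modality, region) pair. Keywords are matched
# on word boundaries after normalization and must be uniquely identifying:
# no keyword may appear under two modalities or under two regions.
modalities:
  CT: [ct, cat scan, computed tomography]
  Ultrasound: [ultrasound, us, sonogram, sonography, sono, duplex, doppler]
  MRI: [mri, mr, magnetic resonance]
  Radiograph: [x-ray, xray, radiograph, plain film, portable film]
regions:
  abdomen: [abdomen, abdominal, abd, pelvis, pelvic, rlq, ruq, llq, luq, gallbladder, liver, appendix, abdominopelvic]
  chest: [chest, thorax, thoracic, lung, lungs, rib]
  head: [head, brain, cranial, skull]
  extremity: [extremity, arm, leg, wrist, ankle, knee, hip, shoulder]
special:
  mrcp:
    modality: MRI
    region: abdomen
  magnetic resonance cholangiopancreatography:
    modality: MRI
    region: abdomen
  ct urography:
    modality: CT
    region: abdomen
  ct urogram:
    modality: CT
    region: abdomen
  kub:
    modality: Radiograph
    region: abdomen
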