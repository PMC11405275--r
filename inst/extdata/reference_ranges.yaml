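# Standard adult reference ranges for the shipped laboratory vocabulary,
# used by the synthetic case generator and by the rendered observations.
# low/high are inclusive bounds; unit strings follow common US lab usage.
white blood cell count: {low: 4.0, high: 11.0, unit: "K/uL"}
hemoglobin: {low: 12.0, high: 17.5, unit: "g/dL"}
hematocrit: {low: 36.0, high: 51.0, unit: "%"}
platelet count: {low: 150.0, high: 400.0, unit: "K/uL"}
red blood cell count: {low: 4.2, high: 5.9, unit: "m/uL"}
sodium: {low: 135.0, high: 145.0, unit: "mEq/L"}
potassium: {low: 3.5, high: 5.1, unit: "mEq/L"}
chloride: {low: 96.0, high: 106.0, unit: "mEq/L"}
bicarbonate: {low: 22.0, high: 29.0, unit: "mEq/L"}
urea nitrogen: {low: 7.0, high: 20.0, unit: "mg/dL"}
creatinine: {low: 0.6, high: 1.2, unit: "mg/dL"}
glucose: {low: 70.0, high: 100.0, unit: "mg/dL"}
calcium: {low: 8.5, high: 10.5, unit: "mg/dL"}
magnesium: {low: 1.7, high: 2.2, unit: "mg/dL"}
phosphate: {low: 2.5, high: 4.5, unit: "mg/dL"}
total bilirubin: {low: 0.1, high: 1.2, unit: "mg/dL"}
direct bilirubin: {low: 0.0, high: 0.3, unit: "mg/dL"}
alkaline phosphatase: {low: 44.0, high: 147.0, unit: "IU/L"}
aspartate aminotransferase: {low: 10.0, high: 40.0, unit: "IU/L"}
alanine aminotransferase: {low: 7.0, high: 56.0, unit: "IU/L"}
gamma glutamyltransferase: {low: 8.0, high: 61.0, unit: "IU/L"}
albumin: {low: 3.5, high: 5.0, unit: "g/dL"}
total protein: {low: 6.0, high: 8.3, unit: "g/dL"}
lipase: {low: 13.0, high: 60.0, unit: "IU/L"}
amylase: {low: 28.0, high: 100.0, unit: "IU/L"}
c-reactive protein: {low: 0.0, high: 10.0, unit: "mg/L"}
lactate: {low: 0.5, high: 2.0, unit: "mmol/L"}
inr: {low: 0.8, high: 1.2, unit: ""}
ptt: {low: 25.0, high: 36.5, unit: "sec"}
urine white blood cells: {low: 0.0, high: 5.0, unit: "/hpf"}
urine red blood cells: {low: 0.0, high: 3.0, unit: "/hpf"}
urine nitrite: {low: ~, high: ~, unit: ""}
urine ketones: {low: ~, high: ~, unit: ""}
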