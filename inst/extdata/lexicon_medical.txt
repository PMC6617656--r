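# Custom medical lexicon: domain terms common in VA narratives that a
# general English dictionary may lack. Custom terms are never "corrected".
abdomen
abdominal
anaemia
anemic
asphyxia
aspiration
ayurvedic
bronchitis
cancer
cardiac
cesarean
chemotherapy
chikungunya
cholera
cirrhosis
convulsion
convulsions
dehydration
dengue
diabetes
diabetic
dialysis
diarrhea
diarrhoea
dysentery
eclampsia
edema
epilepsy
fever
gastric
gradually
haemorrhage
hemoglobin
hemorrhage
hepatitis
hypertension
icu
infarction
jaundice
leukemia
malaria
malnourished
malnutrition
measles
meningitis
miscarriage
neonatal
oedema
oxygen
paracetamol
piles
placenta
pneumonia
postpartum
pregnancy
premature
prematurity
rabies
saline
sepsis
septic
smallpox
sonography
tablet
tablets
tetanus
thyroid
tuberculosis
tumor
tumour
typhoid
ulcer
umbilical
vaccination
ventilator
xray
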