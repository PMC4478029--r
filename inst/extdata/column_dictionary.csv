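column,type,unit,min,max,levels,required,description
id,integer,,,,,TRUE,participant identifier
age,numeric,years,40,110,,TRUE,age at echocardiography
sex,categorical,,,,male|female,TRUE,sex
bmi,numeric,kg/m2,10,70,,TRUE,body mass index
smoking,categorical,,,,never|former|current,TRUE,smoking status
copd,logical,,,,,TRUE,chronic obstructive pulmonary disease flag
diabetes,logical,,,,,TRUE,diabetes mellitus flag
hypertension,logical,,,,,TRUE,systemic hypertension flag
af,logical,,,,,TRUE,atrial fibrillation flag
prior_smoking,categorical,,,,never|former|current,FALSE,smoking status at the prior visit (carry-forward source)
prior_copd,logical,,,,,FALSE,COPD flag at the prior visit (carry-forward source)
trv,numeric,m/s,0,7,,TRUE,tricuspid regurgitation peak velocity
trv_reason,categorical,,,,|jet_absent|jet_too_small|not_recorded,TRUE,reason TRV is missing (empty when measured)
ivc_diameter,numeric,mm,3,60,,TRUE,inferior vena cava end-expiratory diameter
ivc_collapse,numeric,fraction,0,1,,TRUE,inspiratory IVC collapse on sniff test
lvedd,numeric,mm,20,90,,TRUE,LV end-diastolic diameter
lvesd,numeric,mm,0,90,,TRUE,LV end-systolic diameter
rvedd,numeric,mm,10,70,,TRUE,basal RV end-diastolic diameter
e_peak,numeric,m/s,0,4,,TRUE,mitral inflow peak E velocity
a_peak,numeric,m/s,0,4,,TRUE,mitral inflow peak A velocity
e_prime,numeric,cm/s,0,30,,TRUE,septal annular early diastolic velocity
dec_time,numeric,ms,40,500,,TRUE,E-wave deceleration time
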