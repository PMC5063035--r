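code,dialect,class_label,human_name
c61z.,PRESCRIPTION_UK_LIKE,SABA,salbutamol inhaler
c62z.,PRESCRIPTION_UK_LIKE,SABA,terbutaline inhaler
c6A1.,PRESCRIPTION_UK_LIKE,LABA_MONO,salmeterol inhaler
c6A2.,PRESCRIPTION_UK_LIKE,LABA_MONO,formoterol inhaler
c651.,PRESCRIPTION_UK_LIKE,ICS_MONO,beclometasone inhaler
c652.,PRESCRIPTION_UK_LIKE,ICS_MONO,budesonide inhaler
c653.,PRESCRIPTION_UK_LIKE,ICS_MONO,fluticasone inhaler
c6B1.,PRESCRIPTION_UK_LIKE,FDC_ICS_LABA,salmeterol+fluticasone inhaler
c6B2.,PRESCRIPTION_UK_LIKE,FDC_ICS_LABA,formoterol+budesonide inhaler
c6C1.,PRESCRIPTION_UK_LIKE,LTRA,montelukast tablet
c6C2.,PRESCRIPTION_UK_LIKE,LTRA,zafirlukast tablet
c31..,PRESCRIPTION_UK_LIKE,XANTHINE,theophylline tablet
c32..,PRESCRIPTION_UK_LIKE,XANTHINE,aminophylline tablet
fe31.,PRESCRIPTION_UK_LIKE,OCS,prednisolone tablet
fe32.,PRESCRIPTION_UK_LIKE,OCS,prednisone tablet
c6D1.,PRESCRIPTION_UK_LIKE,OMALIZUMAB,omalizumab injection
c6D2.,PRESCRIPTION_UK_LIKE,OMALIZUMAB,omalizumab prefilled syringe
c6E1.,PRESCRIPTION_UK_LIKE,TIOTROPIUM,tiotropium inhaler
c6E2.,PRESCRIPTION_UK_LIKE,TIOTROPIUM,tiotropium soft-mist inhaler
c6F1.,PRESCRIPTION_UK_LIKE,INDACATEROL,indacaterol inhaler
c6F2.,PRESCRIPTION_UK_LIKE,INDACATEROL,indacaterol breath-actuated inhaler
dj21.,PRESCRIPTION_UK_LIKE,OTHER,paracetamol tablet
a981.,PRESCRIPTION_UK_LIKE,OTHER,amoxicillin capsule
R03AC02,DISPENSATION_FR_LIKE,SABA,salbutamol inhaler
R03AC03,DISPENSATION_FR_LIKE,SABA,terbutaline inhaler
R03AC12,DISPENSATION_FR_LIKE,LABA_MONO,salmeterol inhaler
R03AC13,DISPENSATION_FR_LIKE,LABA_MONO,formoterol inhaler
R03BA01,DISPENSATION_FR_LIKE,ICS_MONO,beclometasone inhaler
R03BA02,DISPENSATION_FR_LIKE,ICS_MONO,budesonide inhaler
R03BA05,DISPENSATION_FR_LIKE,ICS_MONO,fluticasone inhaler
R03AK06,DISPENSATION_FR_LIKE,FDC_ICS_LABA,salmeterol+fluticasone inhaler
R03AK07,DISPENSATION_FR_LIKE,FDC_ICS_LABA,formoterol+budesonide inhaler
R03DC03,DISPENSATION_FR_LIKE,LTRA,montelukast tablet
R03DC01,DISPENSATION_FR_LIKE,LTRA,zafirlukast tablet
R03DA04,DISPENSATION_FR_LIKE,XANTHINE,theophylline tablet
R03DA05,DISPENSATION_FR_LIKE,XANTHINE,aminophylline tablet
H02AB06,DISPENSATION_FR_LIKE,OCS,prednisolone tablet
H02AB07,DISPENSATION_FR_LIKE,OCS,prednisone tablet
R03DX05,DISPENSATION_FR_LIKE,OMALIZUMAB,omalizumab injection
R03DX05-150,DISPENSATION_FR_LIKE,OMALIZUMAB,omalizumab 150mg pack
R03BB04,DISPENSATION_FR_LIKE,TIOTROPIUM,tiotropium inhaler
R03BB04-RS,DISPENSATION_FR_LIKE,TIOTROPIUM,tiotropium soft-mist inhaler
R03AC18,DISPENSATION_FR_LIKE,INDACATEROL,indacaterol inhaler
R03AC18-BR,DISPENSATION_FR_LIKE,INDACATEROL,indacaterol breath-actuated inhaler
N02BE01,DISPENSATION_FR_LIKE,OTHER,paracetamol tablet
J01CA04,DISPENSATION_FR_LIKE,OTHER,amoxicillin capsule
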