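sample_id,analyte,value,unit,error
Amphitheater_2017,temperature,35.4,degC,
Amphitheater_2017,pH,3.76,pH,
Amphitheater_2017,specific_conductance,308.0,uS_cm,
Amphitheater_2017,sulfide,210,uM,
Amphitheater_2017,dissolved_oxygen,2.0,uM,
Amphitheater_2017,silica,2.6,mM,
Amphitheater_2017,fluoride,0.0031,mM,
Amphitheater_2017,chloride,0.079,mM,
Amphitheater_2017,bromide,0.13,uM,
Amphitheater_2017,sulfate,1.0,mM,
Amphitheater_2017,nitrate,0.13,uM,
Amphitheater_2017,lithium,3.1,uM,
Amphitheater_2017,sodium,0.97,mM,
Amphitheater_2017,potassium,0.43,mM,
Amphitheater_2017,magnesium,0.056,mM,
Amphitheater_2017,calcium,0.13,mM,
Amphitheater_2017,ammonium,32,uM,
Amphitheater_2017,ferrous_iron,57,uM,
Amphitheater_2017,formate,2.5,uM,
Amphitheater_2017,acetate,0.83,uM,
Amphitheater_2017,DIC,11,mM,
Amphitheater_2017,d13C_DIC,-3.5,permil,0.2
Amphitheater_2017,DOC,0.12,mM,
Amphitheater_2017,d13C_DOC,-25.4,permil,0.2
Amphitheater_2017,mat_C_wt_pct,9.11,wt_pct,0.07
Amphitheater_2017,d13C_mat,-26.4,permil,0.1
Amphitheater_2017,mat_N_wt_pct,1.315,wt_pct,0.007
Amphitheater_2017,d15N_mat,-2.8,permil,0.1
Amphitheater_2017,d2H_H2O,-136.3,permil,0.6
Amphitheater_2017,d18O_H2O,-18.0,permil,0.2
Amphitheater_2014,temperature,38.0,degC,
Amphitheater_2014,pH,3.52,pH,
Amphitheater_2014,specific_conductance,422.6,uS_cm,
Amphitheater_2014,sulfide,120,uM,
Amphitheater_2014,dissolved_oxygen,8.9,uM,
Amphitheater_2014,silica,2.5,mM,
Amphitheater_2014,fluoride,0.0065,mM,
Amphitheater_2014,chloride,0.10,mM,
Amphitheater_2014,bromide,0.12,uM,
Amphitheater_2014,sulfate,1.3,mM,
Amphitheater_2014,nitrate,0.93,uM,
Amphitheater_2014,lithium,4.0,uM,
Amphitheater_2014,sodium,1.2,mM,
Amphitheater_2014,potassium,0.53,mM,
Amphitheater_2014,magnesium,0.075,mM,
Amphitheater_2014,calcium,0.18,mM,
Amphitheater_2014,ammonium,34,uM,
Amphitheater_2014,ferrous_iron,53,uM,
Amphitheater_2014,DIC,7.9,mM,
Amphitheater_2014,d13C_DIC,-4.3,permil,0.2
Amphitheater_2014,DOC,0.13,mM,
Amphitheater_2014,d13C_DOC,-24.5,permil,0.3
Amphitheater_2014,mat_C_wt_pct,10.63,wt_pct,0.07
Amphitheater_2014,d13C_mat,-26.1,permil,0.1
Amphitheater_2014,mat_N_wt_pct,1.355,wt_pct,0.005
Amphitheater_2014,d15N_mat,-4.9,permil,0.1
Amphitheater_2014,d2H_H2O,-140.1,permil,0.3
Amphitheater_2014,d18O_H2O,-18.0,permil,0.1
Lemonade_Creek,temperature,12.6,degC,
Lemonade_Creek,pH,5.28,pH,
Lemonade_Creek,specific_conductance,50.1,uS_cm,
Lemonade_Creek,sulfide,0.65,uM,
Lemonade_Creek,dissolved_oxygen,180,uM,
Lemonade_Creek,silica,1.0,mM,
Lemonade_Creek,fluoride,0.0026,mM,
Lemonade_Creek,chloride,0.016,mM,
Lemonade_Creek,bromide,0.032,uM,
Lemonade_Creek,sulfate,0.058,mM,
Lemonade_Creek,nitrate,0.15,uM,
Lemonade_Creek,lithium,0.17,uM,
Lemonade_Creek,sodium,0.082,mM,
Lemonade_Creek,potassium,0.045,mM,
Lemonade_Creek,magnesium,0.034,mM,
Lemonade_Creek,calcium,0.073,mM,
Lemonade_Creek,ammonium,0.41,uM,
Lemonade_Creek,ferrous_iron,0.36,uM,
Lemonade_Creek,DIC,2.1,mM,
Lemonade_Creek,d13C_DIC,-6.4,permil,0.4
Lemonade_Creek,DOC,0.16,mM,
Lemonade_Creek,d13C_DOC,-26.7,permil,0.2
Lemonade_Creek,d2H_H2O,-133.0,permil,0.6
Lemonade_Creek,d18O_H2O,-17.7,permil,0.2
Hot_Spring_Basin,temperature,37.2,degC,
Hot_Spring_Basin,pH,2.95,pH,
Hot_Spring_Basin,specific_conductance,1021,uS_cm,
Hot_Spring_Basin,sulfide,90,uM,
Hot_Spring_Basin,dissolved_oxygen,16,uM,
Hot_Spring_Basin,silica,2.9,mM,
Hot_Spring_Basin,fluoride,0.022,mM,
Hot_Spring_Basin,chloride,0.021,mM,
Hot_Spring_Basin,bromide,0.060,uM,
Hot_Spring_Basin,sulfate,4.2,mM,
Hot_Spring_Basin,nitrate,0.62,uM,
Hot_Spring_Basin,lithium,3.0,uM,
Hot_Spring_Basin,sodium,1.1,mM,
Hot_Spring_Basin,potassium,0.58,mM,
Hot_Spring_Basin,magnesium,0.11,mM,
Hot_Spring_Basin,calcium,0.23,mM,
Hot_Spring_Basin,ammonium,280,uM,
Hot_Spring_Basin,ferrous_iron,50,uM,
Hot_Spring_Basin,formate,2.3,uM,
Hot_Spring_Basin,acetate,0.99,uM,
Hot_Spring_Basin,DIC,6.0,mM,
Hot_Spring_Basin,d13C_DIC,-3.5,permil,0.2
Hot_Spring_Basin,DOC,0.088,mM,
Hot_Spring_Basin,d13C_DOC,-25.4,permil,0.6
Hot_Spring_Basin,mat_C_wt_pct,12.0,wt_pct,0.3
Hot_Spring_Basin,d13C_mat,-25.6,permil,0.1
Hot_Spring_Basin,mat_N_wt_pct,0.58,wt_pct,0.01
Hot_Spring_Basin,d15N_mat,-5.9,permil,0.1
Hot_Spring_Basin,d2H_H2O,-136.9,permil,0.7
Hot_Spring_Basin,d18O_H2O,-17.3,permil,0.1
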