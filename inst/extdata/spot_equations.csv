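equation_id,sex,component,term,coefficient,unit,provenance
kawasaki,any,main,scale,16.3,mmol/day per sqrt(mmol/day),Kawasaki et al. 1993 Clin Exp Pharmacol Physiol 20:7-14
kawasaki,M,predicted_creatinine,intercept,-79.9,mg/day,Kawasaki et al. 1993
kawasaki,M,predicted_creatinine,age,-12.63,mg/day per year,Kawasaki et al. 1993
kawasaki,M,predicted_creatinine,weight,15.12,mg/day per kg,Kawasaki et al. 1993
kawasaki,M,predicted_creatinine,height,7.39,mg/day per cm,Kawasaki et al. 1993
kawasaki,F,predicted_creatinine,intercept,-74.5,mg/day,Kawasaki et al. 1993
kawasaki,F,predicted_creatinine,age,-4.72,mg/day per year,Kawasaki et al. 1993
kawasaki,F,predicted_creatinine,weight,8.58,mg/day per kg,Kawasaki et al. 1993
kawasaki,F,predicted_creatinine,height,5.09,mg/day per cm,Kawasaki et al. 1993
tanaka,any,main,scale,21.98,mmol/day,Tanaka et al. 2002 J Hum Hypertens 16:97-103
tanaka,any,main,exponent,0.392,dimensionless,Tanaka et al. 2002
tanaka,any,predicted_creatinine,intercept,-2244.45,mg/day,Tanaka et al. 2002
tanaka,any,predicted_creatinine,age,-2.04,mg/day per year,Tanaka et al. 2002
tanaka,any,predicted_creatinine,weight,14.89,mg/day per kg,Tanaka et al. 2002
tanaka,any,predicted_creatinine,height,16.14,mg/day per cm,Tanaka et al. 2002
intersalt_with_k,M,main,intercept,25.46,mmol/day,Brown et al. 2013 Am J Epidemiol 177:1180-1192 (Northern Europe)
intersalt_with_k,M,main,spot_na,0.46,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,M,main,spot_cr_mmol,-2.75,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,M,main,spot_k,-0.13,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,M,main,bmi,4.10,mmol/day per kg/m2,Brown et al. 2013
intersalt_with_k,M,main,age,0.26,mmol/day per year,Brown et al. 2013
intersalt_with_k,F,main,intercept,5.07,mmol/day,Brown et al. 2013
intersalt_with_k,F,main,spot_na,0.34,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,F,main,spot_cr_mmol,-2.16,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,F,main,spot_k,-0.09,mmol/day per mmol/L,Brown et al. 2013
intersalt_with_k,F,main,bmi,2.39,mmol/day per kg/m2,Brown et al. 2013
intersalt_with_k,F,main,age,2.35,mmol/day per year,Brown et al. 2013
intersalt_with_k,F,main,age_sq,-0.03,mmol/day per year2,Brown et al. 2013
intersalt_without_k,M,main,intercept,23.51,mmol/day,Brown et al. 2013 (no potassium form)
intersalt_without_k,M,main,spot_na,0.45,mmol/day per mmol/L,Brown et al. 2013
intersalt_without_k,M,main,spot_cr_mmol,-3.09,mmol/day per mmol/L,Brown et al. 2013
intersalt_without_k,M,main,bmi,4.16,mmol/day per kg/m2,Brown et al. 2013
intersalt_without_k,M,main,age,0.22,mmol/day per year,Brown et al. 2013
intersalt_without_k,F,main,intercept,3.74,mmol/day,Brown et al. 2013
intersalt_without_k,F,main,spot_na,0.33,mmol/day per mmol/L,Brown et al. 2013
intersalt_without_k,F,main,spot_cr_mmol,-2.44,mmol/day per mmol/L,Brown et al. 2013
intersalt_without_k,F,main,bmi,2.42,mmol/day per kg/m2,Brown et al. 2013
intersalt_without_k,F,main,age,2.34,mmol/day per year,Brown et al. 2013
intersalt_without_k,F,main,age_sq,-0.03,mmol/day per year2,Brown et al. 2013
mage,M,predicted_creatinine,scale,1.93,mg/day per kg^1.5 m^0.5,Mage et al. 2008 J Expo Sci Environ Epidemiol 18:360-368
mage,F,predicted_creatinine,scale,1.64,mg/day per kg^1.5 m^0.5,Mage et al. 2008
toft,M,predicted_creatinine,intercept,879.89,mg/day,Ix et al. 2011 Clin J Am Soc Nephrol 6:184-191 (as applied by Toft et al. 2014 Eur J Prev Cardiol 21:1300-1307)
toft,M,predicted_creatinine,weight,12.51,mg/day per kg,Ix et al. 2011
toft,M,predicted_creatinine,age,-6.19,mg/day per year,Ix et al. 2011
toft,F,predicted_creatinine,intercept,500.47,mg/day,Ix et al. 2011 (879.89 - 379.42 female offset)
toft,F,predicted_creatinine,weight,12.51,mg/day per kg,Ix et al. 2011
toft,F,predicted_creatinine,age,-6.19,mg/day per year,Ix et al. 2011
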