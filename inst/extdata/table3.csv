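category,resource,unit,value_eur,is_wage,societal_only
wage,general_practitioner,hour,54,TRUE,FALSE
wage,higher_official_politician,hour,45,TRUE,FALSE
wage,qualified_nurse,hour,33,TRUE,FALSE
wage,primary_care_nurse,hour,26,TRUE,FALSE
wage,public_health_official,hour,25,TRUE,FALSE
wage,other_primary_healthcare_personnel,hour,24,TRUE,FALSE
wage,project_coordinator,hour,22,TRUE,FALSE
wage,assistant_nurse,hour,22,TRUE,FALSE
average_wage,public_health_office_personnel,hour,39,TRUE,FALSE
average_wage,primary_care_personnel,hour,33,TRUE,FALSE
average_wage,employed_other_sectors,hour,54,TRUE,FALSE
patient,time,hour,6,FALSE,TRUE
patient,fees,visit,11,FALSE,TRUE
other,standard_medical_testing,number,20,FALSE,FALSE
other,photocopies,number,0.26,FALSE,FALSE
other,meeting_room,number,13,FALSE,FALSE
other,fruit_basket,number,13,FALSE,FALSE
other,coffee_incl_cake,per_20_people,26,FALSE,FALSE
other,lunch,number,9,FALSE,FALSE
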