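column,type,levels,required,description
case_id,string,,yes,Opaque case identifier
assessment_date,date,,yes,Initial assessment date (ISO-8601)
reassessment_date,date,,no,Reassessment date (ISO-8601); empty if never reassessed
recipient_gender,binary,0|1,yes,Care recipient gender (1 = female)
recipient_age,integer,,yes,Care recipient age in years
disability_certificate,binary,0|1,yes,Recipient holds a disability certificate
dementia,binary,0|1,yes,Recipient has a dementia diagnosis
foreign_caregiver,binary,0|1,yes,Household employs a foreign caregiver
cms_level,integer,1-8,yes,Case-mix system disability level (higher = more disabled)
caregiver_relationship,category,adult_child|spouse|child_in_law|other,yes,Primary caregiver's relationship to the recipient
caregiver_age,integer,,yes,Primary caregiver age in years
alone_duration,category,over_9h|6_to_9h|3_to_6h|1_to_3h|under_1h|cannot_be_alone,yes,How long the recipient can be left alone per 24 h
physical_burden,category,yes|no,yes,Caregiving is a physical strain
sleep_disturbance,category,yes|no,yes,Caregiver's sleep is disturbed
qol_self_rating,category,excellent|very_good|good|fair|bad|very_bad,yes,Caregiver's self-rated quality of life
other_family_care,category,yes|no,yes,Caregiver must also care for other family members
behavior_distress,category,yes|no,yes,Distress from the recipient's behavior
emotional_behavioral_issues,category,yes|no,yes,Recipient has emotional/behavioral issues (caregiver's view)
work_affected,category,yes|no,yes,Caregiving affects the caregiver's work
cannot_cope,category,yes|no,yes,Caregiver feels unable to cope with caregiving stress
reassess_alone_duration,category,over_9h|6_to_9h|3_to_6h|1_to_3h|under_1h|cannot_be_alone,no,Reassessment item; empty if never reassessed
reassess_physical_burden,category,yes|no,no,Reassessment item
reassess_sleep_disturbance,category,yes|no,no,Reassessment item
reassess_qol_self_rating,category,excellent|very_good|good|fair|bad|very_bad,no,Reassessment item
reassess_other_family_care,category,yes|no,no,Reassessment item
reassess_behavior_distress,category,yes|no,no,Reassessment item
reassess_emotional_behavioral_issues,category,yes|no,no,Reassessment item
reassess_work_affected,category,yes|no,no,Reassessment item
reassess_cannot_cope,category,yes|no,no,Reassessment item
psi_1,binary,0|1,no,Screening-indicator flag 1 (present only for post-2022 records)
psi_2,binary,0|1,no,Screening-indicator flag 2
psi_3,binary,0|1,no,Screening-indicator flag 3
psi_4,binary,0|1,no,Screening-indicator flag 4
psi_5,binary,0|1,no,Screening-indicator flag 5
psi_6,binary,0|1,no,Screening-indicator flag 6
psi_7,binary,0|1,no,Screening-indicator flag 7
psi_8,binary,0|1,no,Screening-indicator flag 8
psi_9,binary,0|1,no,Screening-indicator flag 9
psi_10,binary,0|1,no,Screening-indicator flag 10
expert_vote_1,binary,0|1,no,First expert's high-burden vote
expert_vote_2,binary,0|1,no,Second expert's high-burden vote
expert_vote_3,binary,0|1,no,Third expert's high-burden vote
feat_*,numeric,,no,Wide assessment feature block (binary/ordinal/continuous)
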