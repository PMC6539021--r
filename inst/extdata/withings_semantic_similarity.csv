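dataset_attr,fhir_attr,score_pct
identifier,Observation.identifier,56
identifier,Patient.identifier,39
status,Observation.status,81
status,DiagnosticReport.status,17
category,Observation.category,74
category,DiagnosticReport.category,21
sub-category,Observation.code,44
sub-category,Observation.category,32
patient,Observation.subject,39
patient,Patient,34
patient.identifier,Observation.subject.identifier,54
patient.identifier,Patient.identifier,43
patient.name,Observation.subject.name,53
patient.name,Patient.name,47
dateOfMeasurement,DiagnosticReport.effectiveDateTime,53
dateOfMeasurement,Observation.effectiveDateTime,36
practitioner,Observation.subject,63
practitioner,Practitioner,22
practitioner.identifier,Observation.subject.identifier,68
practitioner.identifier,Practitioner.identifier,15
practitioner.name,Observation.subject.name,74
practitioner.name,Practitioner.name,19
measuredValue,Observation.valueQuantity,100
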