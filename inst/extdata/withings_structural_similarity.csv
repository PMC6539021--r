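dataset_attr,fhir_attr,score_pct
identifier,Observation.identifier,54
identifier,DiagnosticReport.identifier,23
status,Observation.status,61
status,DiagnosticReport.status,34
category,Observation.category,29
category,DiagnosticReport.category,22
sub-category,Observation.category,34
sub-category,DiagnosticReport.category,28
patient,Patient,100
patient.identifier,Patient.identifier,100
patient.name,Patient.name,100
dateOfMeasurement,Observation.effectiveDateTime,56
dateOfMeasurement,Observation.valueDateTime,32
practitioner,Practitioner,100
practitioner.identifier,Practitioner.identifier,100
practitioner.name,Practitioner.name,100
measuredValue,Observation.valueQuantity,82
measuredValue,Observation.valueRange,13
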