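Observation.identifier
Observation.status
Observation.category
Observation.code
Observation.subject
Observation.subject.identifier
Observation.subject.name
Observation.effectiveDateTime
Observation.valueDateTime
Observation.valueQuantity
Observation.valueRange
DiagnosticReport.identifier
DiagnosticReport.status
DiagnosticReport.category
DiagnosticReport.effectiveDateTime
Patient
Patient.identifier
Patient.name
Practitioner
Practitioner.identifier
Practitioner.name
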