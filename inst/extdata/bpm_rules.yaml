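# Default element constraints of a blood-pressure monitor observation record.
- element: date
  type: string
  required: yes
  constraint: format
  pattern: '^\d{4}-\d{2}-\d{2}$'
- element: time
  type: string
  required: yes
  constraint: format
  pattern: '^\d{2}:\d{2}:\d{2}$'
- element: diastolic_bp_code
  type: uuid
  required: yes
  constraint: unique_id
- element: diastolic_bp_value
  type: integer
  required: no
  constraint: range
  min: 40.0
  max: 120.0
- element: diastolic_bp_unit
  type: string
  required: no
  constraint: fixed
  fixed: mmHg
- element: systolic_bp_code
  type: uuid
  required: yes
  constraint: unique_id
- element: systolic_bp_value
  type: integer
  required: no
  constraint: range
  min: 70.0
  max: 200.0
- element: systolic_bp_unit
  type: string
  required: no
  constraint: fixed
  fixed: mmHg
- element: heart_rate_code
  type: uuid
  required: yes
  constraint: unique_id
- element: heart_rate_value
  type: integer
  required: no
  constraint: range
  min: 30.0
  max: 220.0
- element: heart_rate_unit
  type: string
  required: no
  constraint: fixed
  fixed: bpm
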