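# iotqa

Quality assessment and FHIR interoperability for IoT medical-device data.

Consumer vital-sign devices (blood-pressure monitors, oximeters, scales)
stream observation records that are dirty — malformed timestamps,
impossible readings, missing fields, transmission gaps — and of unknown
reliability. `iotqa` turns such streams into high-quality, interoperable
clinical data in four stages:

1. **Ingest** — lossless JSON ↔ XML device-dataset I/O
   (`read_device_dataset()`, `convert_to_xml()`).
2. **Clean** — rule-based validation against a declarative constraint table
   (formats, ranges, fixed units, UUID codes), record dropping on
   required-element breaches, kNN imputation for erroneous values and
   C4.5-style decision-tree imputation for missing ones
   (`clean_dataset()`). The report carries the three cleaning metrics:

   - accuracy = (records − actions) / records
   - faulty = 1 − accuracy
   - completion = (records − dropped) / records

3. **Quality gate** — operational availability (uptime / operating cycle),
   the faulty-data fraction, and ICC(2,1) test–retest reliability
   (two-way random effects, absolute agreement, single measurement,
   computed natively from the ANOVA mean squares) combine as

   overall = (availability − faulty) × 0.7 + ICC × 0.3

   on the percent scale; a device is kept only when overall quality
   strictly exceeds 90 % (`quality_report()`, `quality_gate()`).
4. **Map to FHIR** — cleaned XML is lifted to an ontology tree and matched
   to a bundled FHIR R4 attribute catalogue by the mean of structural
   similarity (Sørensen–Dice over overlapping character bigrams) and
   semantic similarity (harmonic mean of precision and recall under a
   pluggable synonym-lexicon backend); matches above 90 % are accepted
   directly, others fall back to the argmax (`match_dataset()`), and kept
   records are emitted as FHIR Observation bundles (`to_fhir()`).

A seeded synthetic stream generator (`generate_stream()`,
`make_table_fixture()`) replaces the Bluetooth hardware layer: it emulates
a monitor at a fixed cadence with truncated-Gaussian vitals and injects
erroneous / missing / absent records at exact configured counts, so every
stage is testable end to end.

## Worked example

```r
library(iotqa)

ds <- make_table_fixture("Withings BPM")   # 61 days x 4 records/day
ds
#> <device_dataset> Withings BPM: 244 records over 61 days (expected 244)

cl <- clean_dataset(ds)
cl$report
#> <cleaning_report> Withings BPM
#>   records: 244 -> 243 (dropped 1), actions: 20 (corrected 19)
#>   accuracy 91.80%  faulty 8.20%  completion 99.59%

qr <- quality_report(cl$report, expected = operating_cycle(ds),
                     icc_pct = bpm_device_icc()[["Withings BPM"]])
qr
#> <quality_report> Withings BPM
#>   availability 99.59%  faulty 8.20%  ICC 95.00%  overall 92.47% -> KEEP
```

Of the 244 expected records, 20 carried anomalies; one (a missing
heart-rate code, a required element) forced a record drop and the other 19
were corrected in place, giving 91.80 % accuracy and 99.59 % completion.
Availability uses the post-cleaning count (243/244 = 99.59 %), and the
weighted combination with the device's reliability input (ICC 95 %) gives
an overall quality of 92.47 % — above the 90 % gate, so the device's data
proceeds to FHIR mapping:

```r
tabs <- reference_similarity_tables()
m <- map_attributes(tabs$structural, tabs$semantic,
                    catalogue = fhir_catalogue())
head(m$selection[, 1:4], 4)
#>        dataset_attr                     fhir_attr  mean        decision
#> 1          category          Observation.category 0.515 argmax_fallback
#> 2 dateOfMeasurement Observation.effectiveDateTime 0.460 argmax_fallback
#> 3        identifier        Observation.identifier 0.550 argmax_fallback
#> 4     measuredValue     Observation.valueQuantity 0.910 above_threshold
```

`measuredValue → Observation.valueQuantity` clears the 90 % threshold
directly; every other attribute is assigned its best-scoring candidate.
`run_pipeline(run_config(...), inputs)` chains all four stages over many
devices, discards gate failures, and writes cleaned XML, report CSVs, FHIR
JSON/XML and a manifest.

See `vignettes/iotqa-methods.Rmd` for the full methodology: metric
definitions, imputation parameters, the reliability-matrix layout, the
similarity model, and what the synthetic generator does and does not
emulate.

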