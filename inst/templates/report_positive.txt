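GENETIC TEST REPORT
===================
Sample:   {{SAMPLE_ID}}
Referral: {{CATEGORY}}
Result:   {{OUTCOME}}

Candidate variants
------------------
{{CANDIDATE_TABLE}}

Copy-number findings
--------------------
{{CNV_TABLE}}

Orthogonal confirmation
-----------------------
{{CONFIRMATION_SECTION}}

Variants are reported in HGVS nomenclature where available. Findings flagged
for confirmation were observed at sequencing depth below the laboratory
threshold and require an independent assay before clinical use.
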