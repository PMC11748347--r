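GENETIC TEST REPORT
===================
Sample:   {{SAMPLE_ID}}
Referral: {{CATEGORY}}
Result:   {{OUTCOME}}

No causative variants were identified in the genes analysed for the referred
phenotype. This result does not exclude a genetic cause: variants outside the
analysed regions, variant types not assayed by panel sequencing, or genes not
yet associated with the phenotype may still explain the presentation.
Periodic reanalysis against updated gene panels is recommended.

Candidate variants
------------------
{{CANDIDATE_TABLE}}

Copy-number findings
--------------------
{{CNV_TABLE}}

Orthogonal confirmation
-----------------------
{{CONFIRMATION_SECTION}}
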