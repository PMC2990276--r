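# Editable predicate templates restricting searches to relation families.
biological:
  - ASSOCIATED_WITH
  - INTERACTS_WITH
  - STIMULATES
  - INHIBITS
  - CAUSES
  - COEXISTS_WITH
  - AUGMENTS
  - DISRUPTS
  - PREDISPOSES
clinical:
  - TREATS
  - PREVENTS
  - DIAGNOSES
  - ADMINISTERED_TO
  - LOCATION_OF
  - ISA
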