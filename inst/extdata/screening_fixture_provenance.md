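# Screening ledger fixture — provenance notes

`screening_fixture.csv` transcribes the published per-category record-ID
lists of the MIMIC screening bookkeeping table (seven categories: three
missing-signal, three abnormal-signal, one included/good). The printed
per-category counts — 284 missing-ABP, 9 missing-ECG, 22 missing-PPG,
114 abnormal-ABP, 21 abnormal-ECG, 7 abnormal-PPG, 121 good; 578 total —
are treated as the authoritative claim; typography is normalized to match
them. Every edit made during transcription:

1. **`s29199s1004` → `s29199`, `s1004`** (abnormal-ABP list). The printed
   list runs two IDs together without a comma; splitting restores the
   printed category count of 114. Both halves are plausible record IDs and
   appear nowhere else.

2. **`44496` → `a44496`** (included list). The only unprefixed numeric token
   in the table; every neighboring ID in that run carries the `a` prefix.

3. **`s07614` duplicate → `s07614-dup`** (abnormal-ABP list). `s07614` is
   printed in *both* the abnormal-ABP list and the included list. The
   per-subject correlation results list subject 7614 among the 121 included
   subjects, corroborating the included copy, so the included entry keeps
   the real ID. The abnormal-ABP occurrence is almost certainly a
   transcription slip for some other record; since the true ID is
   unknowable, the entry is retained as the clearly marked placeholder
   `s07614-dup` so the printed count (114) and the one-category-per-record
   invariant both hold. Any analysis keyed on real record IDs should ignore
   this placeholder.

No other tokens were altered; with these three edits the list lengths equal
the printed counts exactly and no ID appears in two categories.
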