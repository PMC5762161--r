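# Packaged example data

Both files are verbatim transcriptions of the fully printed datasets from a
laboratory study of neoadjuvant radiotherapy (RT) and lymph-node size in
colorectal cancer: six subjects received a short course of RT before
resection surgery ("Short RT"), six comparable subjects did not ("None").
Treatment is applied at the subject level, so the subject is the
experimental unit.

## lymph_size.csv (continuous)

Lymph-node sizes in mm. Each resection specimen was divided into two
sub-samples, processed on different occasions, and three 5 mm slices were
imaged per sub-sample: 12 subjects x 2 samples x 3 slices = 72 records.

Transcription checks: group mean None = 2.40278 mm, Short RT = 2.12028 mm;
subject 1 sample 1 slice 1 = 1.71 mm.

## lymph_count.csv (binomial)

Number of five randomly selected lymph nodes per region of interest with
maximum diameter >= 2 mm (events out of trials = 5), for up to five tissue
samples per subject. Some subjects had insufficient tissue for all five
samples, so the design is unbalanced ("-" cells in the printed table are
absent records): 50 records, 25 per group.

Transcription checks: total events 79 of 125 (None) and 43 of 125
(Short RT); subject 7 samples read (1, 0, 0, 0, 0); subject 8 has two
samples only.
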