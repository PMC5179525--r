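# Reported per-subfamily LRR-RLK gene counts: Arabidopsis thaliana
# (reference lineage) versus Amborella trichopoda (query lineage), with the
# reported expansion ratio R = n_reference / n_query rounded to 1 decimal.
subfamily	n_reference	n_query	ratio_reported
I	41	5	8.2
II	14	6	2.3
III	41	16	2.6
IV	3	1	3
V	9	2	4.5
VI-1	5	3	1.7
VI-2	4	1	4
VII-1	2	1	2
VII-2	5	3	1.7
VIII-1	8	4	2
VIII-2	12	3	4
IX	4	3	1.3
X	15	9	1.7
XI	32	24	1.3
XII	7	7	1
XIII-1	3	3	1
XIII-2	3	1	3
XV	2	2	1
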