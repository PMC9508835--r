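# Loop initiation penalties, kcal/mol at 37 C, by loop type and number of
# unpaired nucleotides. Sizes beyond 30 are extrapolated at run time as
# dg(n) = dg(30) + 1.75*RT*ln(n/30) (Jacobson-Stockmayer).
# Multibranch loops use an affine model (offset + per-branch + per-unpaired)
# with parameters held in the energy model object, not in this file.
type	size	dg
hairpin	3	5.4
hairpin	4	5.71
hairpin	5	5.951
hairpin	6	6.148
hairpin	7	6.314
hairpin	8	6.458
hairpin	9	6.585
hairpin	10	6.699
hairpin	11	6.801
hairpin	12	6.895
hairpin	13	6.982
hairpin	14	7.061
hairpin	15	7.136
hairpin	16	7.206
hairpin	17	7.271
hairpin	18	7.333
hairpin	19	7.391
hairpin	20	7.446
hairpin	21	7.499
hairpin	22	7.549
hairpin	23	7.597
hairpin	24	7.643
hairpin	25	7.687
hairpin	26	7.729
hairpin	27	7.77
hairpin	28	7.809
hairpin	29	7.847
hairpin	30	7.884
bulge	1	3.8
bulge	2	4.548
bulge	3	4.985
bulge	4	5.295
bulge	5	5.536
bulge	6	5.733
bulge	7	5.899
bulge	8	6.043
bulge	9	6.17
bulge	10	6.284
bulge	11	6.386
bulge	12	6.48
bulge	13	6.566
bulge	14	6.646
bulge	15	6.721
bulge	16	6.79
bulge	17	6.856
bulge	18	6.917
bulge	19	6.976
bulge	20	7.031
bulge	21	7.084
bulge	22	7.134
bulge	23	7.182
bulge	24	7.228
bulge	25	7.272
bulge	26	7.314
bulge	27	7.355
bulge	28	7.394
bulge	29	7.432
bulge	30	7.468
internal	2	4
internal	3	4.437
internal	4	4.748
internal	5	4.988
internal	6	5.185
internal	7	5.351
internal	8	5.495
internal	9	5.622
internal	10	5.736
internal	11	5.839
internal	12	5.933
internal	13	6.019
internal	14	6.099
internal	15	6.173
internal	16	6.243
internal	17	6.308
internal	18	6.37
internal	19	6.428
internal	20	6.484
internal	21	6.536
internal	22	6.586
internal	23	6.634
internal	24	6.68
internal	25	6.724
internal	26	6.766
internal	27	6.807
internal	28	6.846
internal	29	6.884
internal	30	6.921
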