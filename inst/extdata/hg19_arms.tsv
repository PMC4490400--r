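# hg19 chromosome arm coordinates; boundaries at centromere gap midpoints
chrom	arm	start	end
chr1	p	1	125000000
chr1	q	125000001	249250621
chr2	p	1	93300000
chr2	q	93300001	243199373
chr3	p	1	91000000
chr3	q	91000001	198022430
chr4	p	1	50400000
chr4	q	50400001	191154276
chr5	p	1	48400000
chr5	q	48400001	180915260
chr6	p	1	61000000
chr6	q	61000001	171115067
chr7	p	1	59900000
chr7	q	59900001	159138663
chr8	p	1	45600000
chr8	q	45600001	146364022
chr9	p	1	49000000
chr9	q	49000001	141213431
chr10	p	1	40200000
chr10	q	40200001	135534747
chr11	p	1	53700000
chr11	q	53700001	135006516
chr12	p	1	35800000
chr12	q	35800001	133851895
chr13	p	1	17900000
chr13	q	17900001	115169878
chr14	p	1	17600000
chr14	q	17600001	107349540
chr15	p	1	19000000
chr15	q	19000001	102531392
chr16	p	1	36600000
chr16	q	36600001	90354753
chr17	p	1	24000000
chr17	q	24000001	81195210
chr18	p	1	17200000
chr18	q	17200001	78077248
chr19	p	1	26500000
chr19	q	26500001	59128983
chr20	p	1	27500000
chr20	q	27500001	63025520
chr21	p	1	13200000
chr21	q	13200001	48129895
chr22	p	1	14700000
chr22	q	14700001	51304566
chrX	p	1	60600000
chrX	q	60600001	155270560
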