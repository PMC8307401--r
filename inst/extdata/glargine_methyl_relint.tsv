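peak	lantus_1	lantus_2	lantus_3	lantus_4	lantus_5	basaglar_1	basaglar_2	basaglar_3	basaglar_4	basaglar_5	p_printed
Ala-a	17.5	20.7	19.8	20.8	23.4	20.2	17.0	22.7	20.8	17.6	0.61
Ala-b	18.0	19.0	17.4	18.1	19.5	16.3	18.8	17.3	18.7	20.7	0.96
Ile-a	30.2	34.7	32.7	30.6	32.8	34.5	33.2	29.6	35.5	32.4	0.54
Ile-b	35.3	34.5	33.6	32.5	33.3	34.9	34.3	32.2	34.1	33.3	0.92
Ile-c	20.1	21.9	19.2	17.8	17.4	20.9	21.1	15.5	18.3	21.0	0.96
Ile-d	20.0	16.8	17.8	16.9	18.0	19.8	20.8	17.2	15.2	20.2	0.57
Ile-e	16.9	15.9	16.4	17.3	19.2	19.3	15.7	16.5	16.7	17.9	0.93
Ile-f	29.8	32.3	27.4	30.4	31.9	30.6	31.4	35.0	28.7	30.7	0.52
Ile-g	32.0	31.4	30.6	30.9	34.6	31.0	32.6	31.8	31.0	30.4	0.54
Leu-a	27.6	26.4	26.7	27.2	30.7	29.1	27.9	25.4	26.6	30.8	0.84
Leu-b	52.8	52.0	48.8	49.4	50.7	50.9	49.3	50.3	46.5	50.3	0.28
Leu-c	36.9	37.6	36.3	39.3	38.4	39.9	35.9	38.0	38.3	37.2	0.88
Leu-d	25.7	25.9	26.7	24.8	25.8	26.6	25.3	27.0	27.0	27.2	0.11
Leu-e	22.0	17.7	18.8	20.9	21.1	23.4	20.9	22.3	19.4	20.0	0.35
Leu-f	22.5	18.8	21.6	21.2	24.0	23.6	25.7	22.1	18.5	22.3	0.58
Leu-g	41.1	41.1	39.6	41.7	46.2	44.7	43.6	43.5	40.8	45.7	0.26
Leu-h	23.3	26.6	23.6	25.6	25.8	25.9	24.6	21.2	21.6	25.7	0.35
Leu-i	20.1	22.2	16.9	21.1	24.8	21.3	21.0	21.1	20.2	19.9	0.83
Leu-j	46.4	50.1	44.5	49.9	52.0	51.8	50.8	48.3	49.6	51.1	0.28
Leu-k	21.7	25.4	21.7	23.1	23.0	26.2	22.1	23.7	24.9	22.6	0.38
Leu-l	42.4	41.8	41.6	41.3	42.3	43.9	41.4	37.5	38.0	42.9	0.43
Leu-m	31.2	31.0	32.7	31.2	33.9	34.2	34.6	29.1	32.9	36.0	0.34
Leu-n	36.2	38.2	37.2	38.4	42.3	40.8	37.6	37.3	40.5	40.5	0.52
Leu-o	18.1	17.6	18.8	21.4	18.5	18.8	17.3	20.2	21.6	17.7	0.85
Leu-p	30.6	30.6	29.4	28.0	28.1	31.7	28.7	24.7	26.4	30.8	0.57
Leu-q	19.1	21.8	19.7	16.1	18.3	18.6	19.9	15.1	16.7	18.7	0.38
Leu-r	24.2	22.7	23.0	21.9	21.5	22.6	24.7	23.5	20.5	22.2	0.96
Leu-s	15.3	19.1	18.4	17.3	21.4	15.7	17.9	15.6	18.9	21.0	0.75
Leu-t	23.0	25.3	23.7	25.3	22.4	21.7	21.5	21.6	19.6	21.3	0.0055
Leu-u	42.5	38.8	40.1	41.6	42.2	43.2	40.2	42.2	42.8	47.5	0.17
Thr-a	45.8	45.8	41.2	40.9	42.8	43.8	41.9	44.8	42.4	46.0	0.73
Thr-b	27.2	27.0	24.0	25.0	25.0	24.1	25.8	26.1	25.9	25.5	0.83
Thr-c	39.4	45.2	42.5	43.8	46.1	45.9	44.2	47.3	44.7	44.3	0.21
Thr-d	100	100	100	100	100	100	100	100	100	100	n/a
Thr-e	64.0	65.5	61.5	64.8	67.4	68.5	68.0	64.5	65.5	66.9	0.13
Thr-f	60.2	61.1	59.0	58.8	61.9	65.1	64.5	58.8	58.1	60.7	0.46
Val-a	22.5	21.6	22.1	19.1	20.0	22.3	21.7	18.7	20.6	21.3	0.85
Val-b	92.1	91.1	87.1	88.6	91.4	91.2	86.6	87.4	88.4	89.6	0.29
Val-c	67.2	65.7	64.6	68.9	71.8	73.0	70.7	67.1	69.2	69.6	0.2
Val-d	84.8	84.8	82.9	87.1	86.3	89.3	90.4	83.1	85.1	83.9	0.5
Val-e	64.2	65.2	63.6	67.1	65.6	68.1	67.2	62.5	66.4	65.3	0.52
Val-f	20.0	17.8	19.3	18.0	17.4	18.4	17.2	17.3	19.2	17.2	0.34
Val-g	20.9	20.2	21.8	21.3	23.5	20.9	21.6	21.1	22.1	25.1	0.52
Val-h	40.0	37.7	37.8	37.6	39.6	43.3	36.4	40.0	38.3	43.3	0.29
Val-i	15.9	20.7	17.5	17.3	20.0	18.1	19.3	16.4	15.4	17.4	0.42
Val-j	24.0	20.8	21.9	16.8	21.7	22.9	23.2	20.9	20.3	19.4	0.83
Val-k	24.2	21.1	25.7	22.8	23.0	21.5	21.9	24.0	24.3	22.0	0.55
Val-l	15.8	19.9	14.5	17.9	17.7	20.2	13.5	17.1	18.6	18.0	0.84
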