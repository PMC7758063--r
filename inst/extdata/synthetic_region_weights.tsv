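deme	weight
r1	0.062044
r2	0.012936
r3	0.016218
r4	0.018413
r5	0.014322
r6	0.014473
r7	0.031039
r8	0.02103
r9	0.023743
r10	0.059387
r11	0.026029
r12	0.075273
r13	0.061882
r14	0.025646
r15	0.052029
r16	0.027359
r17	0.014826
r18	0.019303
r19	0.022118
r20	0.034579
r21	0.032345
r22	0.030447
r23	0.039895
r24	0.01187
r25	0.039307
r26	0.024082
r27	0.031097
r28	0.02893
r29	0.014242
r30	0.019577
r31	0.001889
r32	0.030631
r33	0.023298
r34	0.021397
r35	0.018345
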