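deme_a	deme_b
r1	r2
r2	r7
r2	r3
r3	r8
r3	r4
r4	r9
r4	r5
r5	r10
r6	r7
r7	r12
r7	r8
r8	r13
r8	r9
r9	r14
r9	r10
r10	r15
r11	r16
r11	r12
r12	r17
r12	r13
r13	r18
r13	r14
r14	r15
r15	r20
r16	r21
r16	r17
r17	r22
r17	r18
r18	r23
r18	r19
r19	r24
r19	r20
r21	r22
r22	r27
r22	r23
r23	r28
r23	r24
r24	r29
r24	r25
r25	r30
r26	r31
r26	r27
r27	r32
r28	r33
r28	r29
r29	r34
r29	r30
r30	r35
r31	r32
r32	r33
r33	r34
r34	r35
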