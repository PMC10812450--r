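sample_id,area,harvesting_date,variety,borer_infection,harvest_number,abts,dpph
G-0604-H,Guariba,2020-06-04,CTC9001,high,1,3.4 ± 0.0,8.8 ± 1.4
G-0604-L,Guariba,2020-06-04,CTC9001,low,1,2.3 ± 0.0,4.7 ± 0.0
G-0703-H,Guariba,2020-07-03,CTC9001,high,1,1.8 ± 0.1,5.3 ± 0.5
G-0703-L,Guariba,2020-07-03,RB966928,low,7,2.2 ± 1.5,6.8 ± 4.1
G-0724-H,Guariba,2020-07-24,RB966928,high,1,ND,ND
G-0724-L,Guariba,2020-07-24,RB966928,low,1,ND,ND
G-0808-H,Guariba,2020-08-08,RB985476,high,1,1.5 ± 0.1,1.4 ± 0.2
G-0808-L,Guariba,2020-08-08,CTC4,low,3,1.5 ± 0.1,1.5 ± 0.3
G-0922-H,Guariba,2020-09-22,CU7870,high,4,1.2 ± 0.0,1.1 ± 0.0
G-0922-L,Guariba,2020-09-22,CU7870,low,4,1.5 ± 0.1,2.1 ± 0.0
G-1014-H,Guariba,2020-10-14,RB985476,high,2,0.9 ± 0.0,1.0 ± 0.1
G-1014-L,Guariba,2020-10-14,SP803280,low,4,1.0 ± 0.0,1.2 ± 0.1
G-1116-H,Guariba,2020-11-16,CU7870,high,1,ND,ND
G-1116-L,Guariba,2020-11-16,CU7870,low,1,ND,ND
V-0604-H,Valparaiso,2020-06-04,RB966928,high,1,3.3 ± 0.0,6.9 ± 0.6
V-0604-L,Valparaiso,2020-06-04,CTC9001,low,1,3.6 ± 0.0,9.1 ± 1.1
V-0703-H,Valparaiso,2020-07-03,CTC15,high,7,1.4 ± 0.1,3.1 ± 1.0
V-0703-L,Valparaiso,2020-07-03,CTC15,low,5,1.7 ± 0.1,4.6 ± 0.2
V-0724-H,Valparaiso,2020-07-24,CU7870,high,2,ND,ND
V-0724-L,Valparaiso,2020-07-24,CTC4,low,1,ND,ND
V-0808-H,Valparaiso,2020-08-08,RB966928,high,3,2.9 ± 0.0,3.8 ± 0.2
V-0808-L,Valparaiso,2020-08-08,CU7870,low,4,2.9 ± 0.1,4.0 ± 0.5
V-0922-H,Valparaiso,2020-09-22,CU7870,high,5,1.2 ± 0.1,1.2 ± 0.2
V-0922-L,Valparaiso,2020-09-22,CU0618,low,3,1.4 ± 0.0,1.4 ± 0.0
V-1014-H,Valparaiso,2020-10-14,CTC15,high,6,2.0 ± 0.0,5.0 ± 0.8
V-1014-L,Valparaiso,2020-10-14,CTC15,low,5,1.3 ± 0.1,2.4 ± 0.5
V-1116-H,Valparaiso,2020-11-16,CU7870,high,2,ND,ND
V-1116-L,Valparaiso,2020-11-16,CTC4,low,1,ND,ND
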