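sample_id,area,collection_date,variety,infection_class,infection_level,harvest_number
G-0604-H,Guariba,2020-06-04,CTC9001,high,7.5,1
G-0604-L,Guariba,2020-06-04,CTC9001,low,2.0,1
G-0703-H,Guariba,2020-07-03,CTC9001,high,7.5,1
G-0703-L,Guariba,2020-07-03,RB966928,low,2.0,7
G-0724-H,Guariba,2020-07-24,RB966928,high,7.5,1
G-0724-L,Guariba,2020-07-24,RB966928,low,2.0,1
G-0808-H,Guariba,2020-08-08,RB985476,high,7.5,1
G-0808-L,Guariba,2020-08-08,CTC4,low,2.0,3
G-0922-H,Guariba,2020-09-22,CU7870,high,7.5,4
G-0922-L,Guariba,2020-09-22,CU7870,low,2.0,4
G-1014-H,Guariba,2020-10-14,RB985476,high,7.5,2
G-1014-L,Guariba,2020-10-14,SP803280,low,2.0,3
G-1116-H,Guariba,2020-11-16,SP803280,high,7.5,5
G-1116-L,Guariba,2020-11-16,SP803280,low,2.0,5
V-0604-H,Valparaiso,2020-06-04,RB966928,high,7.5,1
V-0604-L,Valparaiso,2020-06-04,CTC9001,low,2.0,1
V-0703-H,Valparaiso,2020-07-03,CTC15,high,7.5,7
V-0703-L,Valparaiso,2020-07-03,CTC15,low,2.0,5
V-0724-H,Valparaiso,2020-07-24,CU7870,high,7.5,2
V-0724-L,Valparaiso,2020-07-24,CTC4,low,2.0,1
V-0808-H,Valparaiso,2020-08-08,RB966928,high,7.5,3
V-0808-L,Valparaiso,2020-08-08,CU7870,low,2.0,4
V-0922-H,Valparaiso,2020-09-22,CU7870,high,7.5,5
V-0922-L,Valparaiso,2020-09-22,CU0618,low,2.0,3
V-1014-H,Valparaiso,2020-10-14,CTC15,high,7.5,6
V-1014-L,Valparaiso,2020-10-14,SP813250,low,2.0,7
V-1116-H,Valparaiso,2020-11-16,RB966928,high,7.5,4
V-1116-L,Valparaiso,2020-11-16,CTC4,low,2.0,2
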