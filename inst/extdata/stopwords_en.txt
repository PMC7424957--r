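a
about
above
after
again
against
all
am
an
and
any
are
as
at
be
because
been
before
being
below
between
both
but
by
can
cannot
could
did
do
does
doing
down
during
each
er
few
for
from
further
gonna
got
had
has
have
having
he
her
here
hers
herself
him
himself
his
how
hm
i
if
in
into
is
it
its
itself
just
kind
like
lot
me
more
most
my
myself
no
nor
not
now
of
off
okay
on
once
only
or
other
ought
our
ours
ourselves
out
over
own
really
same
she
should
so
some
such
sort
than
that
the
their
theirs
them
themselves
then
there
these
they
this
those
through
to
too
uh
um
under
until
up
very
was
we
well
were
what
when
where
which
while
who
whom
why
with
would
yeah
you
your
yours
yourself
yourselves
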